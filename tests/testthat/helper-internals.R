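# The tests exercise the neural-network engine and other internal plumbing
# directly; bind those unexported symbols from the installed namespace.

.csfnet_internals <- c(
  "nn_forward", "nn_backward", "nn_params", "zero_grads", "new_param",
  "opt_adam", "opt_step",
  "nn_linear", "nn_relu", "nn_hardswish", "nn_hardsigmoid", "nn_sigmoid",
  "nn_bn1d", "nn_bn2d", "nn_dropout", "nn_seq", "nn_residual", "nn_tap",
  "nn_conv2d", "nn_dwconv2d", "nn_gap", "nn_se2d",
  "nn_se1d", "nn_cbam_channel1d", "nn_eca1d", "nn_nam1d", "nn_attention",
  "mbv3_block", "softmax_rows", "ce_forward_backward",
  "spec_class_counts", "mci_batch", "jet_colormap", "model_forward",
  "model_backward", "model_params", "stats_from_images", "fmt_mean_sd"
)
for (.nm in .csfnet_internals)
  assign(.nm, getFromNamespace(.nm, "csfnet"))
rm(.nm)
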