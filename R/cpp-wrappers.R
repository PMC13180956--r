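# Wrappers for the compiled kernels in src/ops.cpp (glue kept by hand in
# src/RcppExports.cpp).

cpp_im2col <- function(x, H, W, C, N, kh, kw, stride, pad) {
  .Call(`_fusnetcnn_cpp_im2col`, x, H, W, C, N, kh, kw, stride, pad)
}

cpp_col2im <- function(cols, H, W, C, N, kh, kw, stride, pad) {
  .Call(`_fusnetcnn_cpp_col2im`, cols, H, W, C, N, kh, kw, stride, pad)
}

cpp_maxpool <- function(x, H, W, C, N) {
  .Call(`_fusnetcnn_cpp_maxpool`, x, H, W, C, N)
}

cpp_maxpool_bwd <- function(grad, idx, H, W, C, N) {
  .Call(`_fusnetcnn_cpp_maxpool_bwd`, grad, idx, H, W, C, N)
}

cpp_median_filter <- function(x, H, W, C, window) {
  .Call(`_fusnetcnn_cpp_median_filter`, x, H, W, C, window)
}

cpp_mat2feat <- function(m, Ho, Wo, C, N) {
  .Call(`_fusnetcnn_cpp_mat2feat`, m, Ho, Wo, C, N)
}

cpp_feat2mat <- function(x, Ho, Wo, C, N) {
  .Call(`_fusnetcnn_cpp_feat2mat`, x, Ho, Wo, C, N)
}
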