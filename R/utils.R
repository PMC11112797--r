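# Internal helpers shared across modules.

stop_input <- function(...) stop(errorCondition(paste0(...), class = c("mnst_input_error", "mnst_error")))
stop_param <- function(...) stop(errorCondition(paste0(...), class = c("mnst_param_error", "mnst_error")))
stop_valid <- function(...) stop(errorCondition(paste0(...), class = c("mnst_validation_error", "mnst_error")))
stop_join  <- function(...) stop(errorCondition(paste0(...), class = c("mnst_join_error", "mnst_error")))
stop_opt   <- function(msg, trace = NULL) {
  cond <- errorCondition(msg, class = c("mnst_optim_error", "mnst_error"))
  cond$trace <- trace
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_valid(what, " contains non-finite entries")
  invisible(x)
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x * x))

# spectral norm estimate by power iteration on a symmetric PSD matrix
spec_norm_psd <- function(A, iters = 20L) {
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    lam <- sqrt(sum(w * w))
    if (lam == 0) return(0)
    v <- as.numeric(w) / lam
  }
  lam
}
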