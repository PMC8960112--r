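# Internal helpers shared across modules.

#' @importFrom stats median sd mad rnorm runif setNames aggregate complete.cases predict quantile
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' Label convention for short-axis cardiac segmentation masks
#'
#' Integer labels follow the ACDC convention: 0 background, 1 right-ventricular
#' blood pool, 2 left-ventricular myocardium, 3 left-ventricular blood pool.
#'
#' @return Named integer vector mapping structure names to label values.
#' @export
label_convention <- function() {
  c(background = 0L, rv_bloodpool = 1L, lv_myocardium = 2L, lv_bloodpool = 3L)
}

structure_label <- function(structure) {
  conv <- label_convention()
  if (is.numeric(structure)) {
    if (!structure %in% conv) stop2("unknown label value: %s", structure)
    return(as.integer(structure))
  }
  if (!structure %in% names(conv)) {
    stop2("unknown structure '%s' (expected one of %s)",
          structure, paste(names(conv), collapse = ", "))
  }
  conv[[structure]]
}

# Deterministic sub-seed derivation; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587)
}

# Stable content hash (used for session ids and config stamps).
content_hash <- function(x) rlang::hash(x)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
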