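#' voom-style log counts-per-million transform
#'
#' `value(s, f) = log2((count(s, f) + 0.5) / (library_size(s) + 1) * 1e6)`.
#' Zero counts are anchored at `log2(0.5 / (L + 1) * 1e6)` — a value that
#' depends only on the library size, which is what lets class-dependent
#' library sizes alone imprint a class signal on features with no reads.
#' Precision weights (the mean-variance trend) are deliberately omitted:
#' the leakage phenomena studied here live in the values.
#'
#' @param x A [count_matrix] with positive library sizes.
#' @return A [normalized_matrix].
#' @export
voom_logcpm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- x$metadata$library_size
  if (any(lib <= 0)) stop("library_size must be positive for all samples")
  values <- log2((x$counts + 0.5) / (lib + 1) * 1e6)
  dimnames(values) <- dimnames(x$counts)
  normalized_matrix(values,
                    provenance = list(transform = "voom_logcpm", leak_mode = "none"),
                    zero_features = colSums(x$counts) == 0L,
                    library_size = stats::setNames(lib, rownames(x$counts)),
                    source = x)
}

one_hot_design <- function(biological, adjustment) {
  n <- length(biological)
  bio <- factor(biological)
  cols <- list(`(Intercept)` = rep(1, n))
  # deviation (sum-to-zero) coding keeps the intercept at the grand mean
  # under balance, so removing intercept + adjustment centers the output
  add_factor <- function(cols, f, prefix) {
    f <- factor(f)
    if (nlevels(f) > 1L) {
      mm <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1L, drop = FALSE]
      colnames(mm) <- paste0(prefix, seq_len(ncol(mm)))
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    }
    cols
  }
  cols <- add_factor(cols, bio, "bio")
  n_bio <- length(cols)
  if (!is.null(adjustment)) cols <- add_factor(cols, factor(adjustment), "adj")
  X <- do.call(cbind, cols)
  list(X = X, bio_cols = seq(2L, n_bio, length.out = max(0L, n_bio - 1L)),
       rm_cols = c(1L, if (ncol(X) > n_bio) seq(n_bio + 1L, ncol(X))))
}

#' Supervised per-feature normalization, with explicit leaky misuse modes
#'
#' The honest mode (`leak_mode = "none"`) fits, per feature, an ordinary
#' least squares model on a design holding the biological covariate (the
#' label whose effects are to be retained) and the adjustment covariate
#' (e.g. batch, whose effects are removed), and returns the values minus
#' the intercept and adjustment components. With no adjustment variation,
#' the output is simply the centered input.
#'
#' The leaky modes reproduce, as named and documented misuse, the
#' class-tagging artifact observed in published normalized matrices:
#'
#' * `"class_offsets"`: features whose **raw** column is identically zero
#'   additionally receive a per-class constant offset (drawn
#'   `N(0, offset_sd^2)` per class and feature) plus within-class noise
#'   `N(0, noise_sd^2)`. With small `noise_sd` this recreates repeated
#'   identical values within a class — a tag a classifier can exploit even
#'   though the raw data contained no information.
#' * `"libsize_coupling"`: library sizes are first multiplied by a
#'   class-dependent factor (log-normal per class), and the log-CPM
#'   transform is recomputed, so that the zero-count anchor values alone
#'   separate the classes.
#'
#' @param x A [normalized_matrix] (from [voom_logcpm()] or a fixture).
#' @param biological Per-sample biological covariate (class label).
#' @param adjustment Per-sample adjustment covariate, or `NULL`.
#' @param leak_mode `"none"`, `"class_offsets"` or `"libsize_coupling"`.
#' @param offset_sd,noise_sd Class-offset leak parameters.
#' @param libsize_log_sd Log-normal SD of the per-class library-size factor.
#' @param seed Integer seed for the leak generators.
#' @return A [normalized_matrix] with provenance recording the leak mode.
#' @export
supervised_normalize <- function(x, biological, adjustment = NULL,
                                 leak_mode = c("none", "class_offsets", "libsize_coupling"),
                                 offset_sd = 1, noise_sd = 0.05,
                                 libsize_log_sd = 0.5, seed = 1L) {
  stopifnot(inherits(x, "normalized_matrix"))
  leak_mode <- match.arg(leak_mode)
  n <- nrow(x$values)
  stopifnot(length(biological) == n,
            is.null(adjustment) || length(adjustment) == n)
  values <- x$values
  if (leak_mode == "libsize_coupling") {
    if (is.null(x$source)) stop("libsize_coupling requires the source count matrix")
    cls <- factor(biological)
    fac <- with_rng(child_seed(seed, "libsize"),
                    stats::rlnorm(nlevels(cls), 0, libsize_log_sd))
    lib <- x$library_size * fac[as.integer(cls)]
    values <- log2((x$source$counts + 0.5) / (lib + 1) * 1e6)
    dimnames(values) <- dimnames(x$values)
  }
  d <- one_hot_design(biological, adjustment)
  qx <- qr(d$X)
  if (qx$rank < ncol(d$X)) {
    dropped <- colnames(d$X)[qx$pivot[seq(qx$rank + 1L, ncol(d$X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qx, values)
  out <- values - d$X[, d$rm_cols, drop = FALSE] %*% coef[d$rm_cols, , drop = FALSE]
  if (leak_mode == "class_offsets") {
    cls <- factor(biological)
    zf <- which(x$zero_features)
    if (length(zf)) {
      off <- with_rng(child_seed(seed, "class_offsets"), {
        o <- matrix(stats::rnorm(nlevels(cls) * length(zf), 0, offset_sd),
                    nlevels(cls), length(zf))
        e <- matrix(stats::rnorm(n * length(zf), 0, noise_sd), n, length(zf))
        o[as.integer(cls), , drop = FALSE] + e
      })
      out[, zf] <- out[, zf, drop = FALSE] + off
    }
  }
  normalized_matrix(out,
                    provenance = list(transform = "supervised_normalize",
                                      base = x$provenance$transform,
                                      leak_mode = leak_mode,
                                      offset_sd = offset_sd, noise_sd = noise_sd,
                                      libsize_log_sd = libsize_log_sd,
                                      seed = seed),
                    zero_features = x$zero_features,
                    library_size = x$library_size,
                    source = x$source)
}
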