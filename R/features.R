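#' Canonical feature-set names
#'
#' The nine input classes compared in the feature-class experiment:
#' `hand`, `joint`, `muscle` (the signals), `d_hand`, `d_joint`, `d_muscle`
#' (their first derivatives), `X` (= hand + joint + muscle), `dX`, and
#' `X+dX`.
#'
#' @return Character vector of the nine canonical names.
#' @export
feature_set_names <- function() {
  c("hand", "joint", "muscle", "d_hand", "d_joint", "d_muscle",
    "X", "dX", "X+dX")
}

# Expand a canonical name (or vector of class names) into (class, deriv) pairs.
resolve_feature_spec <- function(spec) {
  base <- c("hand", "joint", "muscle")
  expand <- function(s) {
    switch(s,
      "X" = base,
      "dX" = paste0("d_", base),
      "X+dX" = c(base, paste0("d_", base)),
      s)
  }
  out <- unlist(lapply(spec, expand), use.names = FALSE)
  if (anyDuplicated(out)) stop("duplicate feature classes in spec")
  ok <- out %in% c(base, paste0("d_", base))
  if (any(!ok)) stop("unknown feature class: ", paste(out[!ok], collapse = ", "))
  out
}

#' Assemble a design matrix from named feature classes
#'
#' Builds the M x K input matrix for the encoders from a kinematic trace and a
#' feature-set specification. Derivative classes are computed on the fly with
#' [differentiate()]; row m of the result is aligned 1:1 with spike bin m.
#'
#' With `extended_extrinsic = TRUE` the `hand` class additionally carries hand
#' velocity and acceleration (the "positions, velocities, and accelerations"
#' reading of extrinsic input), instead of position only.
#'
#' @param trace a [kinematic_trace] containing the classes `hand`, `joint`,
#'   `muscle` (underived classes only; derivatives are computed internally).
#' @param spec one of [feature_set_names()], or a character vector of class
#'   names (e.g. `c("muscle", "d_muscle")`).
#' @param extended_extrinsic logical; see above.
#' @param lag integer bin lag between kinematics and spikes (default 0): with
#'   `lag = k`, feature row m holds the kinematics from sample `m - k`, edge
#'   rows replicated.
#' @return A numeric matrix of class `feature_matrix` with column names and a
#'   `feature_spec` attribute.
#' @export
assemble_features <- function(trace, spec, extended_extrinsic = FALSE,
                              lag = 0L) {
  stopifnot(inherits(trace, "kinematic_trace"))
  classes <- resolve_feature_spec(spec)
  cc <- channel_classes(trace)
  base_needed <- unique(sub("^d_", "", classes))
  missing_cl <- setdiff(base_needed, names(cc))
  if (length(missing_cl) > 0) {
    stop("trace is missing channel class(es): ",
         paste(missing_cl, collapse = ", "))
  }
  dtrace <- if (any(grepl("^d_", classes)) ||
                (extended_extrinsic && "hand" %in% classes)) {
    differentiate(trace)
  } else NULL
  cols <- list()
  for (cl in classes) {
    if (grepl("^d_", cl)) {
      chans <- paste0("d_", cc[[sub("^d_", "", cl)]])
      cols[[cl]] <- as.matrix(as.data.frame(dtrace)[chans])
    } else {
      block <- as.matrix(as.data.frame(trace)[cc[[cl]]])
      if (cl == "hand" && extended_extrinsic) {
        ddtrace <- differentiate(dtrace)
        vel <- as.matrix(as.data.frame(dtrace)[paste0("d_", cc$hand)])
        acc <- as.matrix(as.data.frame(ddtrace)[paste0("d_d_", cc$hand)])
        block <- cbind(block, vel, acc)
      }
      cols[[cl]] <- block
    }
  }
  fm <- do.call(cbind, cols)
  rownames(fm) <- NULL
  lag <- as.integer(lag)
  if (lag != 0 && nrow(fm) > 0) {
    idx <- pmin(pmax(seq_len(nrow(fm)) - lag, 1L), nrow(fm))
    fm <- fm[idx, , drop = FALSE]
  }
  if (anyNA(fm) || (length(fm) > 0 && any(!is.finite(fm)))) {
    stop("feature matrix contains non-finite entries")
  }
  structure(fm, feature_spec = spec, lag = lag,
            class = c("feature_matrix", class(fm)))
}

#' Standardize a feature matrix on a training partition
#'
#' Centers and scales each column using statistics computed only on
#' `fit_rows` (the training rows of the current fold), then applies them to
#' every row, so held-out rows never leak into the statistics. Zero-variance
#' columns are centered and given scale 1, with a warning.
#'
#' @param fm a `feature_matrix` (or plain matrix).
#' @param fit_rows integer vector of rows to compute statistics on.
#' @return The standardized matrix; attributes `center` and `scale` record the
#'   statistics used.
#' @export
standardize_features <- function(fm, fit_rows = seq_len(nrow(fm))) {
  if (length(fit_rows) == 0) stop("fit_rows must be nonempty")
  ctr <- colMeans(fm[fit_rows, , drop = FALSE])
  scl <- apply(fm[fit_rows, , drop = FALSE], 2, sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero)) {
    warning("zero-variance column(s) scaled by 1: ",
            paste(colnames(fm)[zero], collapse = ", "))
    scl[zero] <- 1
  }
  out <- sweep(sweep(fm, 2, ctr, "-"), 2, scl, "/")
  attributes(out) <- attributes(fm)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
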