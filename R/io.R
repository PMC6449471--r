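#' Session bundle
#'
#' Couples a kinematic trace with its aligned spike-count matrix, optional
#' ground truth (for synthetic sessions), and metadata sufficient to
#' regenerate a synthetic bundle exactly.
#'
#' @param trace a [kinematic_trace].
#' @param counts a spike-count matrix with as many rows as the trace.
#' @param ground_truth optional ground-truth list from [generate_spikes()].
#' @param meta named list of metadata (seeds, configuration).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(trace, counts, ground_truth = NULL, meta = list()) {
  stopifnot(inherits(trace, "kinematic_trace"))
  counts <- as.matrix(counts)
  if (nrow(trace) != nrow(counts)) {
    stop(sprintf("trace (%d samples) and counts (%d bins) are misaligned",
                 nrow(trace), nrow(counts)))
  }
  check_counts(counts)
  structure(list(trace = trace, counts = counts, ground_truth = ground_truth,
                 meta = meta),
            class = "session_bundle")
}

check_counts <- function(counts) {
  if (length(counts) == 0) return(invisible(counts))
  if (any(counts < 0)) stop("spike counts must be non-negative")
  if (any(counts != round(counts))) stop("spike counts must be integers")
  invisible(counts)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d bins x %d neurons, %.1f min @ %g Hz\n",
              nrow(x$counts), ncol(x$counts),
              nrow(x$counts) / sample_rate(x$trace) / 60,
              sample_rate(x$trace)))
  if (!is.null(x$ground_truth)) cat("  ground truth: present\n")
  invisible(x)
}

fmt17 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt17(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a session bundle to a directory
#'
#' Canonical on-disk format: a transparent CSV pair plus JSON metadata —
#' `kinematics.csv` (`time_s` + one column per channel), `spikes.csv`
#' (`time_s` + one integer column per neuron), `ground_truth.csv` (noiseless
#' per-bin rates, when present) and `meta.json` (sample rate, bin width,
#' channel classes, seeds/config). Doubles are serialized at 17 significant
#' digits, so output is bit-stable and round-trip exact.
#'
#' @param bundle a [session_bundle].
#' @param path output directory (created if needed).
#' @return Invisibly, a manifest data.frame of files and their MD5 hashes.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  kin <- as.data.frame(bundle$trace)
  write_num_csv(kin, file.path(path, "kinematics.csv"))
  sp <- data.frame(time_s = fmt17(bundle$trace$time_s))
  cn <- colnames(bundle$counts)
  for (j in seq_len(ncol(bundle$counts))) {
    sp[[cn[j]]] <- as.integer(bundle$counts[, j])
  }
  write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
            quote = FALSE)
  files <- c("kinematics.csv", "spikes.csv", "meta.json")
  gt <- bundle$ground_truth
  meta <- list(
    sample_rate = sample_rate(bundle$trace),
    bin_width = 1 / sample_rate(bundle$trace),
    channel_classes = channel_classes(bundle$trace),
    neuron_ids = colnames(bundle$counts),
    meta = bundle$meta,
    has_ground_truth = !is.null(gt)
  )
  if (!is.null(gt)) {
    rates <- as.data.frame(gt$rates)
    write_num_csv(rates, file.path(path, "ground_truth.csv"))
    files <- c(files, "ground_truth.csv")
    meta$ground_truth <- list(
      tuning = unclass(gt$tuning), baseline = gt$baseline,
      weights = list(dim = dim(gt$weights), data = as.numeric(gt$weights)),
      feature_names = gt$feature_names
    )
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = I(17),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(file.path(path, files))))
  invisible(manifest)
}

#' Read a session bundle from a directory
#'
#' Loads and validates a bundle written by [write_bundle()]. Columns are
#' keyed by header name, counts must be non-negative integers, and the
#' kinematics/spikes row counts must agree.
#'
#' @param path bundle directory.
#' @return A [session_bundle].
#' @export
read_bundle <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  kin <- read.csv(file.path(path, "kinematics.csv"))
  sp <- read.csv(file.path(path, "spikes.csv"))
  cc <- lapply(meta$channel_classes, as.character)
  missing_ch <- setdiff(unlist(cc), names(kin))
  if (length(missing_ch) > 0) {
    stop("kinematics.csv is missing columns: ",
         paste(missing_ch, collapse = ", "))
  }
  if (nrow(kin) != nrow(sp)) {
    stop(sprintf("kinematics has %d rows but spikes has %d", nrow(kin),
                 nrow(sp)))
  }
  trace <- kinematic_trace(kin[, c("time_s", unlist(cc, use.names = FALSE))],
                           sample_rate = meta$sample_rate,
                           channel_classes = cc)
  ids <- as.character(meta$neuron_ids)
  missing_n <- setdiff(ids, names(sp))
  if (length(missing_n) > 0) {
    stop("spikes.csv is missing columns: ", paste(missing_n, collapse = ", "))
  }
  counts <- as.matrix(sp[, ids, drop = FALSE])
  check_counts(counts)
  storage.mode(counts) <- "integer"
  counts <- structure(counts, bin_width = meta$bin_width,
                      class = c("spike_count_matrix", class(counts)))
  gt <- NULL
  if (isTRUE(meta$has_ground_truth)) {
    rates <- as.matrix(read.csv(file.path(path, "ground_truth.csv")))
    w <- meta$ground_truth$weights
    gt <- list(
      tuning = structure(meta$ground_truth$tuning, class = "tuning_spec"),
      baseline = as.numeric(meta$ground_truth$baseline),
      weights = matrix(as.numeric(w$data), nrow = w$dim[1], ncol = w$dim[2]),
      feature_names = as.character(meta$ground_truth$feature_names),
      rates = rates
    )
  }
  session_bundle(trace, counts, ground_truth = gt,
                 meta = as.list(meta$meta))
}
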