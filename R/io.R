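## CSV dialect used throughout: comma-separated, UTF-8, '.' decimal point,
## '#' comment lines ignored.  Responses: one row per stimulus, one column
## per repeat, optional header row and optional leading stimulus-ID column
## (both auto-detected: a header is assumed when the first row contains any
## non-numeric field, an ID column when the first column does).  Numeric
## stimulus IDs are NOT auto-detected; drop them or name them in a header.

parse_csv_body <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  strsplit(lines, ",", fixed = TRUE)
}

is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a response matrix from CSV
#'
#' @param path Path to a CSV file, one stimulus per row, one repeat per
#'   column.  `#` comment lines, an optional header row, and an optional
#'   leading non-numeric stimulus-ID column are handled.  Ragged rows are
#'   rejected (responses must be rectangular).
#' @return A [response_matrix()]; stimulus IDs, when present, become row
#'   names.
#' @export
read_response_csv <- function(path) {
  rows <- parse_csv_body(path)
  widths <- lengths(rows)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1])[1L]
    stop("ragged row ", bad, " in ", path, " (", widths[bad], " fields, ",
         "expected ", widths[1], "): response matrices must be rectangular",
         call. = FALSE)
  }
  has_header <- !all(is_num(rows[[1L]]))
  if (has_header) rows <- rows[-1L]
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  first_col <- vapply(rows, `[[`, character(1), 1L)
  has_ids <- !all(is_num(first_col))
  ids <- if (has_ids) first_col else NULL
  body <- lapply(rows, function(r) if (has_ids) r[-1L] else r)
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(body[[1L]]))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-numeric value '", body[[i]][j], "' at row ", i, ", column ",
           j + has_ids, " of ", path, call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (!is.null(ids)) rownames(mat) <- ids
  response_matrix(mat)
}

#' Read model predictions from CSV
#'
#' @param path CSV with a single column of m numeric predictions (optional
#'   header, `#` comments).
#' @param dof Degrees of freedom to attach, default 1.
#' @return A [predictions()] object.
#' @export
read_predictions_csv <- function(path, dof = 1L) {
  rows <- parse_csv_body(path)
  if (any(lengths(rows) != 1L))
    stop("predictions file must contain a single column", call. = FALSE)
  vals <- vapply(rows, `[[`, character(1), 1L)
  if (!is_num(vals[1L])) vals <- vals[-1L]
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    stop("non-numeric prediction '", vals[which(is.na(num))[1L]], "' at row ",
         which(is.na(num))[1L], " of ", path, call. = FALSE)
  }
  predictions(num, dof = dof)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_response_csv()]: plain comma-separated values, no
#' header, full double precision so a write/read round trip is bit-exact.
#'
#' @param Y Response matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(Y, path) {
  Y <- as_response_matrix(Y)
  lines <- apply(Y, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Batch analysis of a set of recordings
#'
#' Runs the full per-recording report -- corrected estimate, naive
#' estimate, SNR, and (optionally) an ECCI -- over a list of recordings,
#' never aborting the batch on a per-recording failure.  A population
#' summary (means, and the count of intervals spanning the entire \[0, 1\]
#' range, i.e. recordings carrying no information about the fit) is
#' attached as attribute `"summary"`.
#'
#' @param recordings List of recordings; each a list with fields `id`
#'   (unique string), `Y` (response matrix), `preds` (predictions).
#' @param alpha Coverage level for the intervals.
#' @param seed Master integer seed (per-recording substreams).
#' @param ci_method `"ecci"`, `"npboot"`, `"pboot"`, `"bca"`, or `"none"`.
#' @param n_samples,chain_length,max_splits ECCI tuning knobs.
#' @param B Bootstrap resamples (bootstrap methods only).
#' @param wide_threshold Interval length above which a recording is
#'   flagged `wide_ci`, default 0.5.
#' @return Data frame with one row per recording: `id`, `m`, `n`,
#'   `r2_er`, `r2_naive`, `snr_hat`, `unstable`, `ci_low`, `ci_high`,
#'   `ci_empty`, `wide_ci`, `status` (`"ok"` or the error message).
#' @export
analyze <- function(recordings, alpha = 0.8, seed = 1L, ci_method = "ecci",
                    n_samples = 2500L, chain_length = 5000L,
                    max_splits = 100L, B = 500L, wide_threshold = 0.5) {
  ids <- vapply(recordings, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids))
    stop("recording ids must be unique", call. = FALSE)
  rows <- lapply(seq_along(recordings), function(k) {
    rec <- recordings[[k]]
    row <- data.frame(id = ids[k], m = NA_integer_, n = NA_integer_,
                      r2_er = NA_real_, r2_naive = NA_real_,
                      snr_hat = NA_real_, unstable = NA,
                      ci_low = NA_real_, ci_high = NA_real_, ci_empty = NA,
                      wide_ci = NA, status = "ok", stringsAsFactors = FALSE)
    tryCatch({
      Y <- as_response_matrix(rec$Y)
      row$m <- nrow(Y); row$n <- ncol(Y)
      fit <- r2_er(Y, rec$preds)
      row$r2_er <- fit$r2_er
      row$r2_naive <- fit$r2_naive
      row$unstable <- fit$unstable
      row$snr_hat <- snr_hat(Y)$snr_hat
      if (ci_method != "none") {
        sk <- substream_seed(seed, k)
        ci <- if (ci_method == "ecci") {
          ecci(Y, rec$preds, r2_er_observed = fit$r2_er, alpha = alpha,
               seed = sk, n_samples = n_samples, max_splits = max_splits,
               chain_length = chain_length)
        } else {
          bootstrap_ci(Y, rec$preds, method = ci_method, alpha = alpha,
                       B = B, seed = sk)
        }
        row$ci_low <- ci$low; row$ci_high <- ci$high; row$ci_empty <- ci$empty
        row$wide_ci <- !ci$empty && (ci$high - ci$low) > wide_threshold
      }
      row
    }, error = function(e) {
      row$status <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$status == "ok"
  attr(out, "summary") <- list(
    n_recordings = nrow(out),
    n_failed = sum(!ok),
    mean_r2_er = mean(out$r2_er[ok]),
    mean_r2_naive = mean(out$r2_naive[ok]),
    mean_snr_hat = mean(out$snr_hat[ok]),
    n_full_range_ci = sum(ok & !is.na(out$ci_low) &
                            out$ci_low <= 0 & out$ci_high >= 1))
  out
}
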