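#' Write / read a spectra dataset as long-format CSV
#'
#' Canonical interchange format: one row per (record, pair, frequency) with
#' columns `subject_id`, `session_id`, `repeat_index`, `temperature_C`,
#' `finger_a`, `finger_b`, `frequency_hz` (integer hertz, avoiding float-key
#' drift) and `impedance_ohm`. The round trip preserves impedances to better
#' than 1e-9 relative (values are written with 15 significant digits).
#'
#' @param ds a `spectra_dataset`.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   a `spectra_dataset`.
#' @export
write_dataset <- function(ds, path) {
  if (!inherits(ds, "spectra_dataset"))
    stop("'ds' must be a spectra_dataset", call. = FALSE)
  df <- as.data.frame(ds)
  df$impedance_ohm <- formatC(df$impedance_ohm, digits = 15, format = "g")
  df$temperature_C <- formatC(df$temperature_C, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need <- c("subject_id", "session_id", "repeat_index", "temperature_C",
            "finger_a", "finger_b", "frequency_hz", "impedance_ohm")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("dataset file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$impedance_ohm) | df$impedance_ohm <= 0)
  if (length(bad))
    stop("non-positive or non-finite impedance at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  key <- paste(df$subject_id, df$session_id, df$repeat_index,
               df$finger_a, df$finger_b, df$frequency_hz)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (subject, session, repeat, pair, frequency) at row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)

  grid <- sort(unique(df$frequency_hz))
  fp <- finger_pairs()
  plab <- pair_label(df$finger_a, df$finger_b)
  if (!all(plab %in% fp$label))
    stop("invalid finger pair encountered (need 1 <= a < b <= 5)",
         call. = FALSE)
  rkey <- paste(df$subject_id, df$session_id, df$repeat_index)
  urec <- unique(rkey)
  n_rec <- length(urec)
  ri <- match(rkey, urec)
  pi <- match(plab, fp$label)
  fi <- match(df$frequency_hz, grid)
  cell <- paste(ri, pi, fi)
  if (nrow(df) != n_rec * nrow(fp) * length(grid) ||
      anyDuplicated(cell))
    stop("every record must contain all 10 pairs at every grid frequency",
         call. = FALSE)
  spectra <- array(NA_real_, dim = c(n_rec, nrow(fp), length(grid)),
                   dimnames = list(NULL, fp$label,
                                   format(grid, scientific = FALSE,
                                          trim = TRUE)))
  spectra[cbind(ri, pi, fi)] <- df$impedance_ohm
  first <- match(urec, rkey)
  meta <- data.frame(subject_id = df$subject_id[first],
                     session_id = df$session_id[first],
                     repeat_index = df$repeat_index[first],
                     temperature = df$temperature_C[first],
                     stringsAsFactors = FALSE)
  new_spectra_dataset(meta, spectra, grid, fp)
}

#' Write / read a ratio combination set as JSON
#'
#' JSON schema: a list of objects `{"num": [a, b], "den": [a, b]}` in
#' combination order.
#'
#' @param combos a [ratio_combination()].
#' @param path file path.
#' @export
write_combination <- function(combos, path) {
  if (!inherits(combos, "ratio_combination"))
    stop("'combos' must be a ratio_combination", call. = FALSE)
  split_lab <- function(l) lapply(strsplit(l, "-", fixed = TRUE),
                                  function(v) as.integer(v))
  obj <- Map(function(n, d) list(num = n, den = d),
             split_lab(combos$num), split_lab(combos$den))
  jsonlite::write_json(unname(obj), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_combination
#' @export
read_combination <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lab <- function(field) vapply(obj, function(o) {
    v <- unlist(o[[field]])
    if (length(v) != 2L) stop("malformed combination file", call. = FALSE)
    pair_label(v[1L], v[2L])
  }, character(1))
  ratio_combination(num = lab("num"), den = lab("den"))
}

#' Write an evaluation report as JSON
#'
#' @param results a named list of `identify_eval` objects (e.g. one per
#'   classifier family).
#' @param path file path.
#' @export
write_report <- function(results, path) {
  rep <- lapply(results, function(r) {
    list(feature_kind = r$feature_kind, classifier = r$classifier,
         n_folds = r$n_folds, accuracy_pct = r$accuracy_pct,
         error_pct = r$error_pct, eer_pct = r$roc$eer_pct, auc = r$roc$auc)
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
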