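#' Write a trial dataset to the long-format trajectory CSV
#'
#' One row per (trial, marker, frame), with the fixed column set
#' `subject_id, trial_id, pronoun, verb_type, verb, is_catch, marker,
#' t_ms, x_mm, y_mm, z_mm`. Times are on the trial clock (0 = verb-stem
#' onset), units are ms and mm, the decimal separator is `.`, the file
#' is UTF-8 with LF line endings. Numeric values are written with
#' round-trip precision, so [read_dataset()] recovers them exactly.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(DATASET_COLUMNS, collapse = ",")
  writeLines(header, con, sep = "\n", useBytes = TRUE)
  for (trial in dataset$trials) {
    meta <- paste(trial$subject_id, trial$trial_id, trial$condition$pronoun,
                  trial$condition$verb_type, trial$condition$verb,
                  tolower(trial$condition$is_catch), sep = ",")
    for (m in names(trial$markers)) {
      tr <- trial$markers[[m]]
      lines <- paste(meta, m, fmt_num(tr$t_ms), fmt_num(tr$x_mm),
                     fmt_num(tr$y_mm), fmt_num(tr$z_mm), sep = ",")
      writeLines(lines, con, sep = "\n", useBytes = TRUE)
    }
  }
  invisible(path)
}

DATASET_COLUMNS <- c("subject_id", "trial_id", "pronoun", "verb_type", "verb",
                     "is_catch", "marker", "t_ms", "x_mm", "y_mm", "z_mm")
MARKER_NAMES <- c("wrist", "index", "thumb")

# %.17g guarantees double -> text -> double round trips
fmt_num <- function(x) sprintf("%.17g", x)

#' Read a trial dataset from the long-format trajectory CSV
#'
#' Reads the dialect written by [write_dataset()]. Rows may appear in
#' any order: frames are sorted by `t_ms` within each (trial, marker)
#' and trials are grouped by (subject, trial). Each trajectory is
#' validated (uniform, strictly increasing sampling).
#'
#' @param path CSV file path.
#' @return A `trial_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = c(1:5, 7)),
                          showProgress = FALSE)
  missing_cols <- setdiff(DATASET_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop("dataset file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_pron <- setdiff(unique(dt$pronoun), PRONOUNS)
  if (length(bad_pron)) {
    stop("unknown pronoun token(s): ", paste(bad_pron, collapse = ", "),
         call. = FALSE)
  }
  bad_vt <- setdiff(unique(dt$verb_type), VERB_TYPES)
  if (length(bad_vt)) {
    stop("unknown verb_type token(s): ", paste(bad_vt, collapse = ", "),
         call. = FALSE)
  }
  bad_mark <- setdiff(unique(dt$marker), MARKER_NAMES)
  if (length(bad_mark)) {
    stop("unknown marker name(s): ", paste(bad_mark, collapse = ", "),
         call. = FALSE)
  }
  is_catch_chr <- tolower(as.character(dt$is_catch))
  if (!all(is_catch_chr %in% c("true", "false"))) {
    stop("`is_catch` must be true/false", call. = FALSE)
  }
  dt$is_catch <- is_catch_chr == "true"

  key <- paste(dt$subject_id, dt$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(dt)), factor(key, levels = unique(key)))
  dt <- as.data.frame(dt)
  trials <- list()
  for (g in groups) {
    rows <- dt[g, ]
    markers <- list()
    for (m in unique(rows$marker)) {
      mr <- rows[rows$marker == m, ]
      ord <- order(mr$t_ms)
      if (anyDuplicated(mr$t_ms)) {
        stop("duplicated frame times in trial ", mr$trial_id[1L],
             " marker ", m, call. = FALSE)
      }
      tr <- tryCatch(
        trajectory(mr$t_ms[ord], mr$x_mm[ord], mr$y_mm[ord], mr$z_mm[ord]),
        error = function(e) {
          stop("invalid trajectory in subject ", mr$subject_id[1L], " trial ",
               mr$trial_id[1L], " marker ", m, ": ", conditionMessage(e),
               call. = FALSE)
        })
      markers[[m]] <- tr
    }
    markers <- markers[intersect(MARKER_NAMES, names(markers))]
    trials[[length(trials) + 1L]] <- trial_record(
      rows$subject_id[1L], rows$trial_id[1L],
      condition(rows$pronoun[1L], rows$verb_type[1L], rows$verb[1L],
                rows$is_catch[1L]),
      markers = markers
    )
  }
  new_trial_dataset(trials)
}

#' Write a per-trial parameter table
#'
#' Tab-separated, one row per trial, the interchange format between the
#' extraction and inference stages.
#'
#' @param params Data frame from [process_dataset()] (optionally after
#'   [apply_qc()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trial_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-trial parameter table written by [write_trial_params()]
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_trial_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "trial_id", "pronoun", "verb_type", "is_catch")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols)) {
    stop("parameter table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out$subject_id <- as.character(out$subject_id)
  out$trial_id <- as.character(out$trial_id)
  out
}
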