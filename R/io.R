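#' Read response sequences from disk
#'
#' Two formats are supported:
#' \describe{
#'   \item{`"csv"`}{columns `participant_id`, `trial`, `response` (an
#'     optional `rep` column from simulated cohorts is folded into the
#'     participant id as `"<id>.r<rep>"`).  Trials must be 1-based,
#'     contiguous and free of duplicates within a participant; rows may
#'     appear in any order.}
#'   \item{`"lines"`}{one digit string per line (e.g. `"352719..."`); only
#'     valid for `K <= 9`.}
#' }
#' Responses outside `1..K` raise a parse error naming the offending line.
#'
#' @param path file to read.
#' @param format `"csv"` or `"lines"`.
#' @param K number of response alternatives.
#' @return A named list of [rng_sequence()] objects.
#' @export
read_sequences <- function(path, format = c("csv", "lines"), K = 9L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  K <- as.integer(K)
  if (format == "lines") {
    if (K > 9L) stop("the lines format supports only K <= 9")
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no sequences in ", path)
    seqs <- lapply(seq_along(lines), function(i) {
      chars <- strsplit(trimws(lines[i]), "")[[1]]
      resp <- suppressWarnings(as.integer(chars))
      if (anyNA(resp) || any(resp < 1L | resp > K))
        stop("line ", i, ": responses must be digits in 1..", K)
      rng_sequence(resp, participant_id = paste0("line", i), K = K)
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "trial", "response")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "))
    id <- as.character(df$participant_id)
    if ("rep" %in% names(df)) id <- paste0(id, ".r", df$rep)
    bad <- which(is.na(df$response) | df$response < 1L | df$response > K)
    if (length(bad))
      stop("response out of range 1..", K, " at data line ", bad[1] + 1L)
    seqs <- lapply(split(seq_len(nrow(df)), id), function(rows) {
      trials <- df$trial[rows]
      if (anyDuplicated(trials))
        stop("duplicate trial index for participant ", id[rows[1]],
             " at data line ", rows[which(duplicated(trials))[1]] + 1L)
      o <- order(trials)
      if (!identical(as.integer(trials[o]), seq_along(rows)))
        stop("trials for participant ", id[rows[1]],
             " are not contiguous starting at 1")
      rng_sequence(df$response[rows][o], participant_id = id[rows[1]], K = K)
    })
  }
  stats::setNames(seqs, vapply(seqs, function(s) s$participant_id,
                               character(1)))
}

#' Write sequences as a CSV of (participant_id, trial, response)
#'
#' @param seqs a list of [rng_sequence()] objects (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (inherits(seqs, "rng_sequence")) seqs <- list(seqs)
  df <- do.call(rbind, lapply(seqs, function(s)
    data.frame(participant_id = s$participant_id,
               trial = seq_along(s$responses), response = s$responses)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model parameters as JSON
#'
#' Serialization is `{"variant": "...", "epsilon": x, ...}` with full
#' double precision, so a round trip returns an equal object.
#'
#' @param params an [model_params()] object.
#' @param path file to write / read.
#' @return `write_model_params`: `path` invisibly; `read_model_params`:
#'   an [model_params()] object.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "rng_model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$variant)) stop("missing 'variant' in ", path)
  do.call(model_params, obj)
}

#' Write a result object to disk
#'
#' Data frames go to TSV with a header; lists (fits, scores,
#' classification results) go to JSON at full double precision.
#'
#' @param object the result to serialize.
#' @param path output file (`.tsv`/`.json` chosen by object type).
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  if (is.data.frame(object)) {
    utils::write.table(object, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else if (is.list(object)) {
    obj <- object
    class(obj) <- NULL
    obj$draws <- NULL  # raw MCMC draws stay in memory, not on disk
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null", force = TRUE)
  } else stop("cannot serialize objects of class ", class(object)[1])
  invisible(path)
}

#' Read a TSV results table
#'
#' @param path file written by [write_results()] for a data frame.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Validated run configuration
#'
#' Collects the knobs shared by the pipeline stages and rejects unknown
#' keys, so a mistyped setting fails before any stage runs.
#'
#' @param ... configuration entries among: `layout` (`"grid3x3"` /
#'   `"line1d"`), `variant`, `chains`, `iter`, `warmup`, `rhat_max`,
#'   `reps`, `length`, `seed`.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(...) {
  defaults <- list(layout = "grid3x3", variant = "cyc3_log", chains = 4L,
                   iter = 1000L, warmup = 1000L, rhat_max = 1.01,
                   reps = 20L, length = 200L, seed = 1L)
  given <- list(...)
  if (length(given) == 1L && is.list(given[[1]]) && is.null(names(given)))
    given <- given[[1]]
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, given)
  cfg$layout <- match.arg(cfg$layout, c("grid3x3", "line1d"))
  cfg$variant <- match.arg(tolower(cfg$variant), model_variants())
  for (k in c("chains", "iter", "warmup", "reps", "length", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  if (cfg$chains < 1L || cfg$iter < 1L || cfg$reps < 1L || cfg$length < 1L)
    stop("chains, iter, reps and length must all be >= 1")
  structure(cfg, class = "run_config")
}
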