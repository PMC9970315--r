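#' Load per-tool miRNA-target prediction tables
#'
#' Reads one delimited file (TSV or CSV, sniffed from the header line) per
#' prediction tool. Each file must have header columns `mirna` and `gene`,
#' with an optional `score` column on the tool's native scale. Identifiers
#' are matched case-insensitively: `mirna` and `gene` are folded to lower
#' case on load, and duplicate rows within a tool are collapsed to one
#' record.
#'
#' @param paths character vector of file paths, one per tool.
#' @param tool_names tool labels; defaults to the file base names.
#' @return A tibble of prediction records with columns `tool`, `mirna`,
#'   `gene` and `score` (`NA` where absent), deduplicated within tool.
#' @seealso [consensus_targets()]
#' @export
load_predictions <- function(paths, tool_names = NULL) {
  paths <- as.character(paths)
  tool_names <- tool_names %||% tools::file_path_sans_ext(basename(paths))
  if (length(tool_names) != length(paths)) {
    abort("`tool_names` must match `paths` in length")
  }
  recs <- Map(function(path, tool) {
    if (!file.exists(path)) abort(sprintf("prediction file not found: %s", path))
    header <- readLines(path, n = 1L)
    if (length(header) == 0L || !nzchar(header)) {
      warn(sprintf("prediction file '%s' is empty", path))
      return(tibble(tool = character(), mirna = character(),
                    gene = character(), score = numeric()))
    }
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    names(tb) <- tolower(names(tb))
    extra <- setdiff(names(tb), c("mirna", "gene", "score"))
    if (length(extra) > 0L) {
      abort(sprintf("unknown column(s) %s in prediction file '%s'",
                    paste(sQuote(extra), collapse = ", "), path))
    }
    if (!all(c("mirna", "gene") %in% names(tb))) {
      abort(sprintf("prediction file '%s' must have columns mirna, gene", path))
    }
    if (nrow(tb) == 0L) {
      warn(sprintf("prediction file '%s' has a header but no rows", path))
    }
    tb <- tibble(tool = tool,
                 mirna = tolower(as.character(tb$mirna)),
                 gene = tolower(as.character(tb$gene)),
                 score = if ("score" %in% names(tb)) as.numeric(tb$score)
                         else NA_real_)
    dplyr::distinct(tb, tool, mirna, gene, .keep_all = TRUE)
  }, paths, tool_names)
  out <- dplyr::bind_rows(recs)
  inform(sprintf("loaded %d prediction records from %d tool file(s)",
                 nrow(out), length(paths)))
  out
}

#' Consensus miRNA-target vote across prediction tools
#'
#' Applies the consensus rule: a gene is kept as a target of a miRNA when at
#' least `min_tools` distinct tools predict the (miRNA, gene) pair, and the
#' per-miRNA target set is the union of all kept pairs. Votes count distinct
#' tools, never duplicate records within a tool.
#'
#' @param records prediction records: a data frame with columns `tool`,
#'   `mirna`, `gene` (for example from [load_predictions()], or
#'   `predictions_to_records()` on a synthetic database).
#' @param min_tools the vote threshold k (default 3, i.e. at least three of
#'   five tools).
#' @return A tibble of class `consensus_targets` with columns `mirna`,
#'   `gene`, `vote_count`, sorted by (mirna, gene); the threshold and tool
#'   set are carried in attributes `min_tools` and `tools`.
#' @examples
#' recs <- tibble::tibble(
#'   tool = c("A", "B", "C", "A", "B"),
#'   mirna = "mir-378a-3p",
#'   gene = c(rep("ctgf", 3), rep("gli3", 2)))
#' consensus_targets(recs, min_tools = 3) # keeps ctgf (3 votes), drops gli3
#' @export
consensus_targets <- function(records, min_tools = 3) {
  records <- as_tibble(records)
  if (!all(c("tool", "mirna", "gene") %in% names(records))) {
    abort("`records` must have columns tool, mirna, gene")
  }
  min_tools <- assert_scalar_count(min_tools, "min_tools", min = 1L)
  n_tools <- dplyr::n_distinct(records$tool)
  if (nrow(records) > 0L && min_tools > n_tools) {
    abort(sprintf("`min_tools` (%d) exceeds the number of distinct tools (%d)",
                  min_tools, n_tools))
  }
  out <- records |>
    dplyr::distinct(.data$tool, .data$mirna, .data$gene) |>
    dplyr::count(.data$mirna, .data$gene, name = "vote_count") |>
    dplyr::filter(.data$vote_count >= min_tools)
  out <- out[lex_order(out$mirna, out$gene), ]
  structure(out,
            min_tools = min_tools,
            tools = lex_sort(unique(records$tool)),
            class = c("consensus_targets", class(out)))
}

#' Flatten a synthetic prediction-table list into prediction records
#'
#' @param predictions named list of per-tool tibbles (`mirna`, `gene`,
#'   optional `score`), as produced by [gen_interaction_db()].
#' @return A tibble with columns `tool`, `mirna`, `gene`, `score`.
#' @export
predictions_to_records <- function(predictions) {
  dplyr::bind_rows(lapply(names(predictions), function(tool) {
    tb <- as_tibble(predictions[[tool]])
    tibble(tool = tool, mirna = as.character(tb$mirna),
           gene = as.character(tb$gene),
           score = if ("score" %in% names(tb)) as.numeric(tb$score)
                   else NA_real_)
  }))
}

#' Write a consensus target set to TSV plus a JSON summary
#'
#' @param x a [consensus_targets()] result.
#' @param tsv_path output TSV path (`mirna`, `gene`, `vote_count`).
#' @param json_path optional path for a JSON summary (tool names, threshold,
#'   per-miRNA target counts).
#' @return `tsv_path`, invisibly.
#' @export
write_consensus <- function(x, tsv_path, json_path = NULL) {
  stopifnot(inherits(x, "consensus_targets"))
  readr::write_tsv(as_tibble(x), tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    per_mirna <- as_tibble(x) |> dplyr::count(.data$mirna, name = "n_targets")
    jsonlite::write_json(list(
      tools = attr(x, "tools"),
      min_tools = attr(x, "min_tools"),
      n_pairs = nrow(x),
      per_mirna = per_mirna
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsv_path)
}
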