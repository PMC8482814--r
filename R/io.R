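#' Read a feature table from TSV
#'
#' Reads a tab-separated sample-by-feature count table. The dominant
#' amplicon convention (features as rows, samples as columns) is the
#' default; set `orientation = "samples_as_rows"` for the transpose. An
#' optional final column named `lineage` holds semicolon-delimited
#' taxonomic ranks; empty rank slots are preserved as empty strings and
#' Greengenes-style two-letter rank prefixes (`g__`, `s__`, ...) are
#' stripped.
#'
#' @param path file path to a TSV table.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`.
#' @param feature_kind `"taxon"` or `"pathway"`.
#' @return a [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows",
                                               "samples_as_rows"),
                               feature_kind = c("taxon", "pathway")) {
  orientation <- match.arg(orientation)
  feature_kind <- match.arg(feature_kind)
  .assert(file.exists(path), "no such file: '%s'", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  .assert(ncol(df) >= 2L, "table '%s' needs an id column and >= 1 data column",
          path)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0L, "duplicate identifier '%s' in '%s'", dup[1L], path)
  df <- df[, -1L, drop = FALSE]

  lineages <- NULL
  if (orientation == "features_as_rows" && ncol(df) > 0L &&
      tolower(colnames(df)[ncol(df)]) == "lineage") {
    lineages <- lapply(df[[ncol(df)]], parse_lineage)
    names(lineages) <- ids
    df <- df[, -ncol(df), drop = FALSE]
  }

  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
                dimnames = list(ids, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop(sprintf(
        "negative or non-numeric cell at row '%s', column '%s' in '%s'",
        ids[bad[1L]], colnames(df)[j], path), call. = FALSE)
    }
    mat[, j] <- v
  }

  if (orientation == "features_as_rows") {
    feature_table(t(mat), feature_kind, lineages)
  } else {
    feature_table(mat, feature_kind, NULL)
  }
}

#' Parse a semicolon-delimited lineage string
#'
#' Splits on `;`, strips surrounding whitespace, preserves empty rank slots
#' and removes two-letter rank prefixes such as `g__` when present.
#'
#' @param x a single lineage string.
#' @return character vector of ranks, domain first.
#' @export
parse_lineage <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  ranks <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  # strsplit drops trailing empty fields; pad them back
  n_slots <- lengths(regmatches(x, gregexpr(";", x, fixed = TRUE))) + 1L
  if (length(ranks) < n_slots) ranks <- c(ranks, rep("", n_slots - length(ranks)))
  sub("^[a-zA-Z]__", "", ranks)
}

#' Read a sample-to-cohort design from TSV
#'
#' Two tab-separated columns: sample id and cohort label. A header line is
#' auto-detected (a first line repeated elsewhere is never treated as a
#' header; one whose second field reoccurs as a label is data). Exact
#' duplicate rows are dropped with a warning; the same sample listed with
#' two different cohorts is an error.
#'
#' @param path file path.
#' @return a [cohort_design] with cohorts ordered by first appearance.
#' @export
read_design <- function(path) {
  .assert(file.exists(path), "no such file: '%s'", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  .assert(ncol(df) >= 2L, "design '%s' needs two columns", path)
  # treat a first row of the conventional header names as a header
  if (nrow(df) > 0L &&
      tolower(df[1L, 1L]) %in% c("sample_id", "sample", "sampleid", "#sampleid")) {
    df <- df[-1L, , drop = FALSE]
  }
  ids <- df[[1L]]
  labels <- df[[2L]]
  dup <- duplicated(ids)
  if (any(dup)) {
    for (id in unique(ids[dup])) {
      labs <- unique(labels[ids == id])
      .assert(length(labs) == 1L,
              "sample '%s' assigned to conflicting cohorts: %s",
              id, paste(labs, collapse = ", "))
    }
    warning(sprintf("dropping %d duplicate design row(s)", sum(dup)),
            call. = FALSE)
    labels <- labels[!dup]
    ids <- ids[!dup]
  }
  cohort_design(stats::setNames(labels, ids))
}

#' Read a feature-by-pathway trait matrix from TSV
#'
#' @param path file path; features as rows, pathways as columns.
#' @return a [trait_matrix].
#' @export
read_trait_matrix <- function(path) {
  tab <- read_feature_table(path, orientation = "samples_as_rows")
  trait_matrix(tab$counts)
}

#' Write a feature table to TSV
#'
#' Features as rows, samples as columns, with a trailing `lineage` column
#' when lineages are present. Output is byte-stable for identical input.
#'
#' @param table a [feature_table].
#' @param path output file path.
#' @export
write_feature_table <- function(table, path) {
  mat <- t(table$counts)
  lines <- c(paste(c("feature_id", colnames(mat),
                     if (!is.null(table$lineages)) "lineage"),
                   collapse = "\t"))
  lin <- table$lineages
  body <- vapply(seq_len(nrow(mat)), function(i) {
    row <- c(rownames(mat)[i], .fmt_num(mat[i, ]))
    if (!is.null(lin)) row <- c(row, paste(lin[[rownames(mat)[i]]], collapse = ";"))
    paste(row, collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Dispatches on the result class; numbers are serialized with at least 10
#' significant digits and identical inputs produce byte-identical files.
#'
#' @param result a result object (`beta_partition`, `core_set`,
#'   `stochasticity_result`, a named list of either, or a data frame).
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  UseMethod("write_results")
}

#' @export
write_results.beta_partition <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(c("beta_sor\tbeta_sim\tbeta_nes\tn_sites",
                 paste(c(.fmt_num(c(result$beta_sor, result$beta_sim,
                                    result$beta_nes)),
                         result$n_sites), collapse = "\t")), path)
  } else {
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_results.stochasticity_result <- function(result, path,
                                               format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    p <- result$pairs
    hdr <- "sample_i\tsample_j\tobserved\texpected\tselection_strength\tstochasticity"
    body <- vapply(seq_len(nrow(p)), function(i) {
      paste(c(p$sample_i[i], p$sample_j[i],
              .fmt_num(c(p$observed[i], p$expected[i],
                         p$selection_strength[i], p$stochasticity[i]))),
            collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_results.core_set <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- list(threshold = result$threshold, inclusive = result$inclusive,
                per_cohort_core = lapply(result$per_cohort_core, as.list),
                venn = lapply(result$venn, as.list),
                core_fraction = as.list(result$core_fraction))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- unlist(lapply(names(result$per_cohort_core), function(co) {
      feats <- result$per_cohort_core[[co]]
      if (length(feats) == 0L) return(character(0))
      paste(co, feats, sep = "\t")
    }))
    writeLines(c("cohort\tfeature_id", rows), path)
  }
  invisible(path)
}

#' @export
write_results.data.frame <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(result, path, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  } else {
    cols <- lapply(result, function(col) {
      if (is.numeric(col)) .fmt_num(col) else as.character(col)
    })
    body <- do.call(paste, c(cols, sep = "\t"))
    writeLines(c(paste(names(result), collapse = "\t"), body), path)
  }
  invisible(path)
}

#' @export
write_results.list <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json" &&
      all(vapply(result, inherits, logical(1), "beta_partition"))) {
    jsonlite::write_json(lapply(result, unclass), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  if (format == "tsv" &&
      all(vapply(result, inherits, logical(1), "beta_partition"))) {
    hdr <- "cohort\tbeta_sor\tbeta_sim\tbeta_nes\tratio\tn_sites"
    body <- vapply(names(result), function(co) {
      b <- result[[co]]
      paste(c(co, .fmt_num(c(b$beta_sor, b$beta_sim, b$beta_nes,
                             b$nestedness_turnover_ratio)),
              b$n_sites), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
    return(invisible(path))
  }
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
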