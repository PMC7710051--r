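#' Read a phenotype + covariate table
#'
#' Reads a CSV with one row per sample: an id column, a trait column, and the
#' declared fixed-effect covariate columns. Categorical covariates keep their
#' level labels; numeric covariates are parsed as numbers. Rows with missing
#' trait values or missing covariates are flagged (columns `missing_y`,
#' `missing_covariate`), never dropped.
#'
#' @param path CSV path.
#' @param id_col Name of the sample-id column.
#' @param trait_col Name of the trait column.
#' @param covariate_cols Character vector of covariate column names; by
#'   default every remaining column.
#' @return Data frame of class `phenotype_table` with columns `id`, `y`, the
#'   covariates, and flag columns; attribute `"covariates"` records the
#'   declared covariate names.
#' @export
read_phenotypes <- function(path, id_col = "id", trait_col = "y",
                            covariate_cols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, trait_col)) {
    if (!col %in% names(df)) {
      stop("column `", col, "` not found in ", path, call. = FALSE)
    }
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(df), c(id_col, trait_col))
  } else if (!all(covariate_cols %in% names(df))) {
    stop("declared covariate column(s) absent: ",
         paste(setdiff(covariate_cols, names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df[[id_col]])) {
    stop("duplicate sample id(s): ",
         paste(head(unique(df[[id_col]][duplicated(df[[id_col]])]), 5),
               collapse = ", "), call. = FALSE)
  }
  y_raw <- df[[trait_col]]
  y <- suppressWarnings(as.numeric(y_raw))
  bad <- !is.na(y_raw) & nzchar(trimws(as.character(y_raw))) & is.na(y)
  if (any(bad)) {
    stop("non-numeric trait value(s): ",
         paste(head(y_raw[bad], 5), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = as.character(df[[id_col]]), y = y,
                    stringsAsFactors = FALSE)
  for (col in covariate_cols) {
    v <- df[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    out[[col]] <- v
  }
  out$missing_y <- is.na(out$y)
  out$missing_covariate <- if (length(covariate_cols)) {
    rowSums(is.na(out[, covariate_cols, drop = FALSE])) > 0
  } else {
    rep(FALSE, nrow(out))
  }
  attr(out, "covariates") <- covariate_cols
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a gene annotation TSV
#'
#' Four tab-separated columns (header optional): symbol, chromosome, start,
#' end; coordinates are 1-based and inclusive on both ends.
#'
#' @param path TSV path.
#' @return A [gene_annotation()] data frame.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("symbol", first, ignore.case = TRUE)
  ann <- read.table(path, header = has_header, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(ann) < 4) stop("annotation needs 4 columns", call. = FALSE)
  gene_annotation(ann[[1]], ann[[2]], ann[[3]], ann[[4]])
}

#' Write a gene annotation TSV
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a gene-symbol lexicon TSV
#'
#' One or two tab-separated columns: symbol, and optionally the canonical
#' symbol it aliases (empty/equal means the row is itself canonical).
#'
#' @param path TSV path.
#' @return A [gene_lexicon()].
#' @export
read_lexicon <- function(path) {
  lx <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   fill = TRUE)
  symbols <- toupper(lx[[1]])
  aliases <- NULL
  if (ncol(lx) >= 2) {
    canon <- toupper(trimws(as.character(lx[[2]])))
    is_alias <- nzchar(canon) & !is.na(canon) & canon != symbols
    if (any(is_alias)) {
      aliases <- setNames(canon[is_alias], symbols[is_alias])
      symbols <- symbols[!is_alias]
    }
  }
  gene_lexicon(symbols, aliases)
}

#' Write a gene-symbol lexicon TSV
#' @param lexicon A [gene_lexicon()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lexicon, path) {
  rows <- data.frame(symbol = lexicon$symbols, canonical = "",
                     stringsAsFactors = FALSE)
  if (length(lexicon$aliases)) {
    rows <- rbind(rows, data.frame(symbol = names(lexicon$aliases),
                                   canonical = unname(lexicon$aliases),
                                   stringsAsFactors = FALSE))
  }
  write.table(rows, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an abstract corpus (JSON Lines)
#'
#' One JSON object per line with fields `id`, `title`, `abstract` and
#' optionally `trait`.
#'
#' @param path JSONL path.
#' @return An [abstract_corpus()].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(abstract_corpus(character(0), character(0), character(0)))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  get <- function(field, default = NA_character_) {
    vapply(recs, function(r) as.character(r[[field]] %||% default), "")
  }
  abstract_corpus(get("id"), get("title", ""), get("abstract", ""),
                  get("trait"))
}

#' Write an abstract corpus as JSON Lines
#' @param corpus An [abstract_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(id = corpus$doc_id[i],
                                     title = corpus$title[i],
                                     abstract = corpus$abstract[i],
                                     trait = corpus$trait[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write a SNP extract list
#'
#' Writes the SNP ids of one partition set, one id per line in map order
#' (the PLINK `--extract` convention).
#'
#' @param partition A [snp_partition()].
#' @param which Set name: `"all"`, `"tm"`, `"exp"` or `"em"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_extract <- function(partition, which, path) {
  stopifnot(inherits(partition, "snp_partition"))
  if (!which %in% c("all", "tm", "exp", "em") ||
      is.null(partition[[which]])) {
    stop("unknown or absent set name: ", which, call. = FALSE)
  }
  idx <- partition[[which]]
  if (!length(idx)) warning("writing empty SNP set `", which, "`")
  writeLines(partition$ids[idx], path)
  invisible(path)
}

#' Read a SNP extract list back to map indices
#'
#' @param path File with one SNP id per line.
#' @param panel A [genotype_panel()] whose map resolves the ids.
#' @return Sorted integer indices into the panel's map.
#' @export
read_snp_extract <- function(path, panel) {
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(ids)]
  idx <- match(ids, panel$map$id)
  if (anyNA(idx)) {
    stop("SNP id(s) not in panel map: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  sort(idx)
}
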