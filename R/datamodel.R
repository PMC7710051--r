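#' Genotype panel constructor
#'
#' Bundles a biallelic dosage matrix with its SNP map and sample ids. Dosages
#' count copies of allele 1 per individual, coded 0/1/2 with `NA` for missing
#' calls (the missing sentinel is never conflated with 0). Positions are
#' 1-based base pairs and must be strictly increasing within each chromosome;
#' chromosome names are opaque labels. All index sets over the map (see
#' [snp_partition()]) are 1-based positions in map order.
#'
#' @param dosage Integer matrix, individuals in rows, SNPs in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param map Data frame with columns `id`, `chr`, `pos`, `a1`, `a2`
#'   (one row per SNP, same order as the columns of `dosage`).
#' @param samples Character vector of sample ids (defaults to
#'   `rownames(dosage)`).
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `map`, `samples`.
#' @export
genotype_panel <- function(dosage, map, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- sprintf("ID%04d", seq_len(nrow(dosage)))
  samples <- as.character(samples)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("id", "chr", "pos", "a1", "a2")
  if (!all(required %in% names(map))) {
    stop("`map` must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dosage) != length(samples)) {
    stop("dosage rows (", nrow(dosage), ") do not match sample count (",
         length(samples), ")", call. = FALSE)
  }
  if (ncol(dosage) != nrow(map)) {
    stop("dosage columns (", ncol(dosage), ") do not match SNP map rows (",
         nrow(map), ")", call. = FALSE)
  }
  if (anyDuplicated(map$id)) {
    stop("duplicate SNP ids in map: ",
         paste(head(unique(map$id[duplicated(map$id)]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
    }
  }
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- samples
  colnames(dosage) <- map$id
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "individuals x",
      nrow(x$map), "SNPs on", length(unique(x$map$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param snps Integer indices into the SNP map (map order), or `NULL` for all.
#' @param samples Integer indices or sample ids, or `NULL` for all.
#' @return A new `genotype_panel` in the induced order.
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(snps)) seq_len(nrow(panel$map)) else as.integer(snps)
  ii <- if (is.null(samples)) {
    seq_along(panel$samples)
  } else if (is.character(samples)) {
    m <- match(samples, panel$samples)
    if (anyNA(m)) stop("unknown sample id(s)", call. = FALSE)
    m
  } else {
    as.integer(samples)
  }
  genotype_panel(panel$dosage[ii, si, drop = FALSE],
                 panel$map[si, , drop = FALSE],
                 panel$samples[ii])
}

#' SNP panel partition
#'
#' Named, disjoint index sets over a panel's SNP map: `tm` (feature /
#' text-mined SNPs), `exp` (its complement), `all`, and optionally `em`
#' (an evenly-spaced control set of the same size as `tm`). Indices are
#' 1-based positions in map order.
#'
#' @param ids Character vector of all SNP ids in map order.
#' @param tm Integer indices of the feature set (may be empty).
#' @param em Optional integer indices of the evenly-spaced control set.
#' @return Object of class `snp_partition` with elements `ids`, `all`, `tm`,
#'   `exp`, `em`.
#' @export
snp_partition <- function(ids, tm = integer(0), em = NULL) {
  ids <- as.character(ids)
  m <- length(ids)
  tm <- sort(unique(as.integer(tm)))
  if (length(tm) && (min(tm) < 1L || max(tm) > m)) {
    stop("tm indices out of range 1..", m, call. = FALSE)
  }
  if (!is.null(em)) {
    em <- sort(unique(as.integer(em)))
    if (length(em) && (min(em) < 1L || max(em) > m)) {
      stop("em indices out of range 1..", m, call. = FALSE)
    }
  }
  structure(list(ids = ids, all = seq_len(m), tm = tm,
                 exp = setdiff(seq_len(m), tm), em = em),
            class = "snp_partition")
}

#' @export
print.snp_partition <- function(x, ...) {
  cat("snp_partition over", length(x$all), "SNPs: |tm| =", length(x$tm),
      ", |exp| =", length(x$exp))
  if (!is.null(x$em)) cat(", |em| =", length(x$em))
  cat("\n")
  invisible(x)
}

#' Attach an evenly-spaced control set to a partition
#'
#' @param partition A [snp_partition()].
#' @param em Integer indices (map order) of the control set, e.g. from
#'   [evenly_spaced_subset()].
#' @return The partition with its `em` slot filled.
#' @export
set_em <- function(partition, em) {
  stopifnot(inherits(partition, "snp_partition"))
  snp_partition(partition$ids, tm = partition$tm, em = em)
}

#' Gene-symbol lexicon
#'
#' The dictionary used for gene-symbol matching: a set of valid (uppercase)
#' symbols plus an optional alias map resolving alternative symbols to their
#' canonical form.
#'
#' @param symbols Character vector of gene symbols (uppercased internally).
#' @param aliases Optional named character vector, `names()` are aliases and
#'   values are canonical symbols; every value must be in `symbols`.
#' @return Object of class `gene_lexicon` with elements `symbols`, `aliases`.
#' @export
gene_lexicon <- function(symbols, aliases = NULL) {
  symbols <- toupper(as.character(symbols))
  symbols <- unique(symbols[nzchar(symbols)])
  if (!length(symbols)) stop("lexicon has no symbols", call. = FALSE)
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      stop("`aliases` must be a named character vector", call. = FALSE)
    }
    aliases <- setNames(toupper(as.character(aliases)), toupper(names(aliases)))
    bad <- setdiff(aliases, symbols)
    if (length(bad)) {
      stop("alias target(s) not in lexicon: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(symbols = symbols, aliases = aliases), class = "gene_lexicon")
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat("gene_lexicon:", length(x$symbols), "symbols,",
      length(x$aliases), "aliases\n")
  invisible(x)
}

#' Gene annotation table constructor
#'
#' @param symbol Character gene symbols.
#' @param chr Chromosome labels.
#' @param start,end 1-based inclusive interval bounds in base pairs.
#' @return Data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(symbol, chr, start, end) {
  ann <- data.frame(symbol = toupper(as.character(symbol)),
                    chr = as.character(chr),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (any(ann$start > ann$end)) {
    stop("annotation has start > end", call. = FALSE)
  }
  if (anyDuplicated(ann[, c("symbol", "chr")])) {
    stop("duplicate (symbol, chromosome) pairs in annotation", call. = FALSE)
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Abstract corpus constructor
#'
#' @param doc_id Unique document identifiers.
#' @param title,abstract Character vectors of title and abstract text.
#' @param trait Optional trait tag (recycled).
#' @return Data frame of class `abstract_corpus`.
#' @export
abstract_corpus <- function(doc_id, title, abstract, trait = NA_character_) {
  if (anyDuplicated(doc_id)) stop("duplicate document ids", call. = FALSE)
  cc <- data.frame(doc_id = as.character(doc_id), title = as.character(title),
                   abstract = as.character(abstract),
                   trait = rep_len(as.character(trait), length(doc_id)),
                   stringsAsFactors = FALSE)
  class(cc) <- c("abstract_corpus", "data.frame")
  cc
}
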