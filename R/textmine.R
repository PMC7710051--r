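#' Extract candidate gene-symbol tokens from text
#'
#' Implements the capital-letters-or-numbers extraction rule used to screen
#' abstract text for gene symbols while discarding ordinary words that merely
#' collide with symbol spellings (e.g. "impact", "pigs"). Text is split on
#' every non-alphanumeric character (so "IGF-1" yields "IGF" and "1"); a
#' token is kept when it consists only of uppercase letters and digits, has
#' at least two characters, and contains at least one letter. Tokens are
#' returned in document order with repeats; matching is case-sensitive, so
#' "Cast" is never a candidate.
#'
#' @param text Character scalar (or vector, concatenated with spaces).
#' @return Character vector of candidate tokens (possibly empty).
#' @export
#' @examples
#' filter_tokens("The IGF1 and CAST genes impact pigs.") # "IGF1" "CAST"
filter_tokens <- function(text) {
  if (!length(text)) return(character(0))
  text <- paste(text, collapse = " ")
  if (!nzchar(text)) return(character(0))
  toks <- strsplit(text, "[^A-Za-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  keep <- grepl("^[A-Z0-9]+$", toks) & nchar(toks) >= 2 & grepl("[A-Z]", toks)
  toks[keep]
}

#' Mine gene symbols from an abstract corpus
#'
#' Runs [filter_tokens()] over each document's title and abstract, maps alias
#' hits to their canonical symbol, and keeps only tokens present in the
#' lexicon. Frequency is the total occurrence count across the corpus by
#' default; `count_mode = "articles"` counts distinct documents instead.
#' Provenance (the document ids containing each symbol) is recorded.
#'
#' @param corpus An [abstract_corpus()].
#' @param lexicon A [gene_lexicon()].
#' @param count_mode `"occurrences"` (default) or `"articles"`.
#' @return Object of class `mined_gene_set`: list with `freq` (named integer
#'   vector, decreasing), `provenance` (list symbol -> document ids),
#'   `trait`, `count_mode`.
#' @export
mine_genes <- function(corpus, lexicon,
                       count_mode = c("occurrences", "articles")) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  count_mode <- match.arg(count_mode)
  if (!length(lexicon$symbols)) stop("empty lexicon", call. = FALSE)
  tally <- new.env(parent = emptyenv())
  prov <- list()
  for (i in seq_len(nrow(corpus))) {
    toks <- filter_tokens(paste(corpus$title[i], corpus$abstract[i]))
    if (!length(toks)) next
    if (length(lexicon$aliases)) {
      hit <- toks %in% names(lexicon$aliases)
      toks[hit] <- unname(lexicon$aliases[toks[hit]])
    }
    toks <- toks[toks %in% lexicon$symbols]
    if (!length(toks)) next
    counts <- table(toks)
    for (sym in names(counts)) {
      add <- if (count_mode == "occurrences") as.integer(counts[[sym]]) else 1L
      prev <- if (exists(sym, tally)) get(sym, tally) else 0L
      assign(sym, prev + add, tally)
      prov[[sym]] <- c(prov[[sym]], corpus$doc_id[i])
    }
  }
  syms <- ls(tally)
  freq <- setNames(vapply(syms, get, 0L, envir = tally), syms)
  ord <- order(-freq, names(freq))
  structure(list(freq = freq[ord], provenance = prov[names(freq[ord])],
                 trait = corpus$trait[1] %||% NA_character_,
                 count_mode = count_mode),
            class = "mined_gene_set")
}

#' @export
print.mined_gene_set <- function(x, ...) {
  cat("mined_gene_set:", length(x$freq), "symbols (", x$count_mode, ")\n")
  print(head(x$freq, 10))
  invisible(x)
}

#' Top-k mined symbols by frequency
#'
#' Ties are broken alphabetically; frequencies are in decreasing order.
#'
#' @param mined A [mine_genes()] result.
#' @param k Number of symbols to return (capped at the set size).
#' @return Data frame with columns `symbol`, `freq`.
#' @export
top_frequency_table <- function(mined, k) {
  stopifnot(inherits(mined, "mined_gene_set"))
  check_scalar(k, "k", lower = 1)
  ord <- order(-mined$freq, names(mined$freq))
  top <- mined$freq[ord][seq_len(min(k, length(mined$freq)))]
  data.frame(symbol = names(top), freq = as.integer(top),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map mined genes to a SNP panel partition
#'
#' A SNP belongs to the feature (`tm`) set when its position lies inside a
#' mined gene's \[start, end\] interval, plus — when `include_intergenic` is
#' set — when it lies in an intergenic interval for which a nearest flanking
#' gene on either side is mined (intergenic stretches are attributed to
#' their flanking gene pair, so a SNP between genes A and B is a feature
#' SNP if A or B is mined; stretches before the first or after the last
#' gene of a chromosome have no flanking pair and are never assigned).
#' `flank_cap_kb`
#' optionally restricts the intergenic reach to a fixed distance from the
#' mined gene's boundary. The complement forms the `exp` set; both are in
#' map order.
#'
#' @param mined A [mine_genes()] result (or character vector of symbols).
#' @param annotation A [gene_annotation()].
#' @param panel A [genotype_panel()].
#' @param include_intergenic Include intergenic SNPs flanked by mined genes
#'   (default `TRUE`).
#' @param flank_cap_kb Cap on intergenic distance from a mined gene, in kb
#'   (default `Inf` = the full interval).
#' @return A [snp_partition()].
#' @export
select_snps <- function(mined, annotation, panel, include_intergenic = TRUE,
                        flank_cap_kb = Inf) {
  stopifnot(inherits(panel, "genotype_panel"))
  symbols <- if (inherits(mined, "mined_gene_set")) {
    names(mined$freq)
  } else {
    toupper(as.character(mined))
  }
  absent <- setdiff(symbols, annotation$symbol)
  if (length(absent)) {
    warning("mined gene(s) absent from annotation, skipped: ",
            paste(head(absent, 10), collapse = ", "))
    symbols <- setdiff(symbols, absent)
  }
  cap_bp <- flank_cap_kb * 1000
  tm <- logical(nrow(panel$map))
  for (ch in unique(panel$map$chr)) {
    snp_i <- which(panel$map$chr == ch)
    if (!length(snp_i)) next
    pos <- panel$map$pos[snp_i]
    genes <- annotation[annotation$chr == ch, , drop = FALSE]
    if (!nrow(genes)) next
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    is_mined <- genes$symbol %in% symbols
    ## inside a mined gene
    for (g in which(is_mined)) {
      tm[snp_i[pos >= genes$start[g] & pos <= genes$end[g]]] <- TRUE
    }
    if (include_intergenic && any(is_mined)) {
      ## flanking regions; running max of ends handles overlapping genes
      ends <- cummax(genes$end)
      ng <- nrow(genes)
      for (g in seq_len(ng)) {
        if (!is_mined[g]) next
        ## upstream gap: between the previous gene's end and this gene's
        ## start (chromosome ends are not intergenic — no flanking pair)
        if (g > 1) {
          lo <- max(ends[g - 1] + 1, genes$start[g] - cap_bp)
          hi <- genes$start[g] - 1
          if (hi >= lo) tm[snp_i[pos >= lo & pos <= hi]] <- TRUE
        }
        ## downstream gap: between this gene's end and the next gene's start
        if (g < ng) {
          lo2 <- ends[g] + 1
          hi2 <- min(genes$start[g + 1] - 1, genes$end[g] + cap_bp)
          if (hi2 >= lo2) tm[snp_i[pos >= lo2 & pos <= hi2]] <- TRUE
        }
      }
    }
  }
  snp_partition(panel$map$id, tm = which(tm))
}
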