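## Filler vocabulary for synthetic abstracts: lowercase prose that can never
## pass the all-caps token filter, plus decoy words that are gene symbols in
## spelling but appear in ordinary (lowercase) usage.
FILLER_WORDS <- c(
  "the", "effect", "of", "selection", "on", "growth", "and", "meat",
  "quality", "traits", "was", "investigated", "in", "a", "commercial",
  "population", "animals", "were", "phenotyped", "for", "carcass",
  "weight", "tenderness", "marbling", "significant", "association",
  "between", "markers", "observed", "heritability", "estimates", "ranged",
  "from", "moderate", "to", "high", "suggesting", "that", "genomic",
  "information", "can", "improve", "accuracy", "breeding", "programs",
  "samples", "collected", "at", "slaughter", "analysed", "using", "mixed",
  "models", "results", "indicate", "polygenic", "architecture", "with",
  "variants", "contributing", "small", "effects")

## All-caps tokens that are not gene symbols (cross-checked against the
## lexicon at run time) — these must survive the token filter yet be
## rejected by dictionary matching.
CAPS_JUNK <- c("TIAB", "PCR", "QTL", "SNP", "GWAS", "BLUP", "AOAC", "NCBI")

#' Simulate an abstract corpus with planted gene symbols
#'
#' Builds `n_docs` filler abstracts and plants each symbol of `planted`
#' exactly its requested number of times, distributed at random over the
#' abstracts. Lowercase decoy words (by default `"impact"` and `"pigs"`,
#' words that collide with gene-symbol spellings in running text) and
#' all-caps non-lexicon tokens are mixed in so that both filter stages of
#' the mining rule are exercised. The returned truth table is the planted
#' count per symbol.
#'
#' @param lexicon A [gene_lexicon()]; every planted symbol must be a member.
#' @param planted Named integer vector: symbol -> occurrence count.
#' @param decoys Lowercase decoy words planted `decoy_count` times each.
#' @param n_docs Number of documents.
#' @param decoy_count Occurrences per decoy word (default 10).
#' @param trait Trait tag stored on every document.
#' @param seed Integer seed.
#' @return List with `corpus` (an [abstract_corpus()]) and `truth` (named
#'   integer vector of planted counts).
#' @export
simulate_corpus <- function(lexicon, planted, decoys = c("impact", "pigs"),
                            n_docs = 20, decoy_count = 10,
                            trait = "trait", seed = 1) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  if (length(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted)))) {
      stop("`planted` must be a named count vector", call. = FALSE)
    }
    names(planted) <- toupper(names(planted))
    known <- c(lexicon$symbols, names(lexicon$aliases))
    bad <- setdiff(names(planted), known)
    if (length(bad)) {
      stop("planted symbol(s) not in lexicon: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (n_docs == 0) {
    return(list(corpus = abstract_corpus(character(0), character(0),
                                         character(0)),
                truth = setNames(integer(0), character(0))))
  }
  set.seed(seed)
  junk <- setdiff(CAPS_JUNK, c(lexicon$symbols, names(lexicon$aliases)))
  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    n_words <- sample(30:60, 1)
    words <- sample(FILLER_WORDS, n_words, replace = TRUE)
    if (length(junk)) {
      words <- append(words, sample(junk, sample(0:2, 1), replace = TRUE),
                      after = sample(length(words), 1))
    }
    docs[[d]] <- words
  }
  ## distribute planted occurrences and decoys over documents
  plant_into <- function(docs, token, count) {
    for (i in seq_len(count)) {
      d <- sample(n_docs, 1)
      at <- sample(length(docs[[d]]), 1)
      docs[[d]] <- append(docs[[d]], token, after = at)
    }
    docs
  }
  for (sym in names(planted)) docs <- plant_into(docs, sym, planted[[sym]])
  for (dc in decoys) docs <- plant_into(docs, dc, decoy_count)

  titles <- vapply(seq_len(n_docs), function(d) {
    paste(sample(FILLER_WORDS, sample(4:8, 1)), collapse = " ")
  }, "")
  abstracts <- vapply(docs, function(w) paste0(paste(w, collapse = " "), "."),
                      "")
  corpus <- abstract_corpus(sprintf("PMID%05d", seq_len(n_docs)),
                            titles, abstracts, trait)
  counts <- if (length(planted)) {
    as.integer(planted)
  } else {
    integer(0)
  }
  list(corpus = corpus, truth = setNames(counts, names(planted)))
}
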