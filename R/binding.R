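#' MHC class I binding predictors
#'
#' Binding calls come from a pluggable predictor: either an adapter over
#' NetMHCpan-4.1-style tabular output, or a built-in deterministic surrogate
#' that maps each (peptide, allele) pair to a uniform percentile rank in
#' [0, 100). A rank strictly below the cutoff (default 2, the NetMHCpan
#' default) marks a binder.
#'
#' @name binding
NULL

#' Deterministic surrogate binding predictor
#'
#' Ranks are uniform on [0, 100): each (peptide, allele, seed) triple is
#' hashed to a 32-bit value that seeds R's RNG for a single uniform draw, so
#' identical inputs always yield identical ranks while ranks across distinct
#' pairs behave as i.i.d. uniforms. An optional per-allele additive offset
#' (on the rank scale) lets tests construct alleles with systematically
#' stronger presentation.
#'
#' @param seed integer surrogate seed
#' @param allele_shift named numeric vector of per-allele rank offsets
#'   (negative = stronger binder); names are normalized allele strings
#' @return a `binding_predictor`
#' @export
surrogate_predictor <- function(seed = 0L, allele_shift = NULL) {
  structure(list(type = "surrogate", seed = as.integer(seed),
                 allele_shift = allele_shift),
            class = "binding_predictor")
}

#' NetMHCpan-file binding predictor
#'
#' Adapter over NetMHCpan-4.1 "-xls"-style tabular output: a tab-separated
#' file with (at least) columns for the peptide, the allele, and the EL
#' percentile rank. Column names are matched case-insensitively against
#' peptide/Peptide, allele/MHC/HLA, and EL_Rank/EL.rank/rank.
#'
#' @param path prediction file
#' @return a `binding_predictor`
#' @export
netmhcpan_file_predictor <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  df <- read_tsv(path)
  pick <- function(cands) {
    hit <- which(tolower(names(df)) %in% tolower(cands))
    if (!length(hit)) stop("prediction file ", path, " lacks a ",
                           cands[1], " column")
    hit[1]
  }
  tab <- data.frame(
    peptide = toupper(df[[pick(c("peptide"))]]),
    allele = normalize_hla(df[[pick(c("allele", "mhc", "hla"))]]),
    rank_score = as.numeric(df[[pick(c("el_rank", "el.rank", "rank"))]]),
    stringsAsFactors = FALSE)
  structure(list(type = "netmhcpan-file", path = path, table = tab),
            class = "binding_predictor")
}

#' @export
print.binding_predictor <- function(x, ...) {
  cat("<binding_predictor>", x$type,
      if (x$type == "surrogate") paste0("(seed ", x$seed, ")") else x$path,
      "\n")
  invisible(x)
}

surrogate_rank <- function(peptide, allele, seed, allele_shift = NULL) {
  n <- length(peptide)
  r <- vapply(seq_len(n), function(i) {
    h <- fnv1a32(paste(peptide[i], allele[i], seed, sep = "|"))
    with_seed(h, runif(1))
  }, 0) * 100
  if (!is.null(allele_shift)) {
    sh <- allele_shift[allele]
    sh[is.na(sh)] <- 0
    r <- pmax(0, r + unname(sh))
  }
  r
}

#' Predict MHC class I binding for peptide/allele pairs
#'
#' Evaluates every (peptide, allele) combination. With a file-based
#' predictor, a requested pair missing from the file is an error (listing
#' the pairs), as is a file row for a pair never requested.
#'
#' @param peptides character vector of peptides
#' @param alleles character vector of HLA class I alleles (any accepted
#'   spelling; normalized via [normalize_hla()])
#' @param predictor a `binding_predictor`
#' @param rank_cutoff binder threshold on the percentile rank (strict <,
#'   default 2.0)
#' @return data.frame: peptide, allele, rank_score, is_binder
#' @export
predict_binding <- function(peptides, alleles, predictor,
                            rank_cutoff = 2.0) {
  stopifnot(inherits(predictor, "binding_predictor"))
  peptides <- unique(toupper(peptides))
  alleles <- unique(normalize_hla(alleles))
  pairs <- expand.grid(peptide = peptides, allele = alleles,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!nrow(pairs))
    return(data.frame(peptide = character(0), allele = character(0),
                      rank_score = numeric(0), is_binder = logical(0)))
  if (predictor$type == "surrogate") {
    rank <- surrogate_rank(pairs$peptide, pairs$allele, predictor$seed,
                           predictor$allele_shift)
  } else {
    tab <- predictor$table
    req_key <- paste(pairs$peptide, pairs$allele)
    tab_key <- paste(tab$peptide, tab$allele)
    extra <- setdiff(tab_key, req_key)
    if (length(extra))
      stop("prediction file contains pair(s) never requested: ",
           paste(utils::head(extra, 3), collapse = "; "))
    idx <- match(req_key, tab_key)
    if (anyNA(idx))
      stop("missing prediction for requested pair(s): ",
           paste(utils::head(req_key[is.na(idx)], 5), collapse = "; "))
    rank <- tab$rank_score[idx]
  }
  data.frame(peptide = pairs$peptide, allele = pairs$allele,
             rank_score = rank, is_binder = rank < rank_cutoff,
             stringsAsFactors = FALSE)
}
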