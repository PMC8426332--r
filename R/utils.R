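#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pchisq pt qnorm rbinom rexp rnbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a private RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state so library code never perturbs user RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, reduced mod 2^31 - 1 so the
# result is always a valid set.seed() argument. Arithmetic stays exact in
# doubles by folding to 16-bit halves before the 2^24-scale multiplies.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(x)) {
    h <- bitwXor32(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

# bitwXor for values that may exceed .Machine$integer.max (fold to 32 bits)
bitwXor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(ah %% 65536, bh %% 65536) * 65536 + bitwXor(al, bl)
}

#' Parse an event id back into its genomic parts
#'
#' Event ids have the form `chrom:start-end:strand:transcript_id`
#' (0-based half-open coordinates). The genomic key drops the transcript.
#' @param event_id character vector of event ids
#' @return data.frame with chrom, start, end, strand, transcript_id, genomic_key
#' @export
parse_event_id <- function(event_id) {
  if (!length(event_id))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      transcript_id = character(0),
                      genomic_key = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(event_id, ":", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed event_id: ", event_id[bad][1])
  chrom <- vapply(parts, `[[`, "", 1L)
  coords <- vapply(parts, `[[`, "", 2L)
  strand <- vapply(parts, `[[`, "", 3L)
  tx <- vapply(parts, function(p) paste(p[-(1:3)], collapse = ":"), "")
  se <- strsplit(coords, "-", fixed = TRUE)
  start <- as.integer(vapply(se, `[[`, "", 1L))
  end <- as.integer(vapply(se, `[[`, "", 2L))
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             transcript_id = tx,
             genomic_key = paste0(chrom, ":", coords, ":", strand),
             stringsAsFactors = FALSE)
}

event_id_of <- function(chrom, start, end, strand, transcript_id) {
  paste0(chrom, ":", start, "-", end, ":", strand, ":", transcript_id)
}

genomic_key_of <- function(event_id) parse_event_id(event_id)$genomic_key

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
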