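# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. `seed = NULL` leaves the
# current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Random DNA string
#'
#' Uniform i.i.d. ACGT sequence, used for euchromatic flanks and test
#' fixtures.
#'
#' @param n Length in bp.
#' @param bases Alphabet to draw from.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# BED-style data.frame (0-based half-open) -> IRanges (1-based closed).
bed_to_ir <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# IRanges -> BED columns.
ir_to_bed <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Total overlap in bp between two BED interval sets (each a data.frame
# with start/end; single chromosome).
overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ia <- IRanges::reduce(bed_to_ir(a$start, a$end))
  ib <- IRanges::reduce(bed_to_ir(b$start, b$end))
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform integer draws in [lo, hi], safe for lo == hi
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
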