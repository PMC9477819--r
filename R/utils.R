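# Shared helpers: DNA strings, 0-based half-open interval arithmetic (via
# IRanges; +1 shift happens here and nowhere else), deterministic sub-seeding.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce a DNAStringSet / character vector to a named uppercase character vector
as_named_dna <- function(x, prefix = "seq") {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    abort("sequences must be a character vector or DNAStringSet")
  }
  if (length(out) == 0L) return(setNames(out, character(0)))
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- if (length(out) == 1L) prefix else paste0(prefix, seq_along(out))
  }
  out
}

# IRanges from 0-based half-open starts/ends
iranges0 <- function(start0, end0) {
  keep <- end0 > start0
  IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep])
}

# total width of the union of 0-based half-open intervals
union_width0 <- function(start0, end0) {
  sum(IRanges::width(IRanges::reduce(iranges0(start0, end0))))
}

# width of the intersection of two 0-based half-open interval sets
intersect_width0 <- function(s1, e1, s2, e2) {
  sum(IRanges::width(IRanges::intersect(
    IRanges::reduce(iranges0(s1, e1)), IRanges::reduce(iranges0(s2, e2)))))
}

# stable 31-bit hash of a string, for per-sample RNG sub-seeds
stable_hash <- function(id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

sub_seed <- function(seed, id, stream = "") {
  as.integer((as.numeric(seed) * 7919 + stable_hash(paste0(id, "/", stream))) %% 2147483647)
}

# introduce substitution errors at a fixed per-base rate; never the same base
mutate_sequence <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}
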