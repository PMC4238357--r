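#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Watson-Crick partners; RNA side uses U internally
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
# DNA base complementary to a given RNA base (the base a probe needs)
DNA_OF_RNA <- c(A = "T", C = "G", G = "C", U = "A")

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

normalize_rna <- function(x) chartr("Tt", "Uu", toupper(x))

normalize_dna <- function(x) chartr("Uu", "Tt", toupper(x))

check_alphabet <- function(x, what = "sequence") {
  bad <- setdiff(unique(seq_chars(normalize_dna(x))), DNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf("invalid character(s) %s in %s", paste(bad, collapse = ","), what))
  }
  invisible(x)
}

#' Reverse complement of a DNA sequence
#' @param x character scalar over A/C/G/T (U accepted, treated as T)
#' @return character scalar, 5'->3'
#' @keywords internal
revcomp_dna <- function(x) {
  x <- normalize_dna(x)
  paste(rev(seq_chars(chartr("ACGT", "TGCA", x))), collapse = "")
}

#' DNA probe complementary to an RNA target
#'
#' Returns the DNA oligonucleotide (5'->3') that is the perfect reverse
#' complement of an RNA-sense target written 5'->3'.
#' @param rna character scalar over A/C/G/U (T accepted as U)
#' @return character scalar DNA 5'->3'
#' @export
probe_for_target <- function(rna) {
  check_alphabet(rna, "RNA target")
  revcomp_dna(normalize_dna(rna))
}

# longest exact common substring length between two short strings (DP scan)
lcs_length <- function(a, b) {
  a <- seq_chars(a); b <- seq_chars(b)
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb)
  best <- 0L
  for (i in seq_len(na)) {
    hit <- a[i] == b
    cur <- integer(nb)
    cur[hit] <- c(0L, prev[-nb])[hit] + 1L
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  best
}

# Longest contiguous match of `query` inside concatenated `haystack`,
# found by checking substring containment from long to short (binary search
# over the monotone predicate), seeded at a minimum reportable length.
longest_match_in <- function(query, haystack, min_len = 1L) {
  n <- nchar(query)
  if (n < min_len || !nzchar(haystack)) return(0L)
  has_match <- function(k) {
    subs <- unique(substring(query, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
    any(vapply(subs, function(s) grepl(s, haystack, fixed = TRUE), logical(1)))
  }
  if (!has_match(min_len)) return(0L)
  lo <- min_len; hi <- n
  while (lo < hi) { # invariant: has_match(lo); largest k with a match
    mid <- (lo + hi + 1L) %/% 2L
    if (has_match(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Shannon entropy (bits) of overlapping dinucleotide composition
dinucleotide_entropy <- function(x) {
  ch <- seq_chars(x)
  if (length(ch) < 2L) return(0)
  dinucs <- paste0(ch[-length(ch)], ch[-1L])
  p <- table(dinucs) / length(dinucs)
  -sum(p * log2(p))
}

# longest self-complementary stem: longest common substring between the
# oligo and its own reverse complement
max_self_stem <- function(x) {
  x <- normalize_dna(x)
  lcs_length(x, revcomp_dna(x))
}

gc_fraction <- function(x) {
  ch <- seq_chars(normalize_dna(x))
  mean(ch %in% c("G", "C"))
}

running_mean <- function(x, width) {
  # mean of x over all windows of `width`; length(x) - width + 1 values
  cs <- cumsum(c(0, x))
  (cs[(width + 1L):length(cs)] - cs[1:(length(cs) - width)]) / width
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}
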