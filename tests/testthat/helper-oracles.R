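# Independent oracles used across the suite. These deliberately avoid the
# code paths of the package functions they check.

# exact binomial upper tail by direct log-space summation of pmf terms
binom_tail_oracle <- function(alt, depth, p) {
  if (alt <= 0) return(1)
  if (alt > depth) return(0)
  i <- alt:depth
  terms <- exp(lchoose(depth, i) + i * log(p) + (depth - i) * log1p(-p))
  sum(rev(terms))  # small terms first
}

# plain Hamming distance on equal-length strings; N matches nothing
hamming_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# textbook Needleman-Wunsch, linear gap; returns aligned strings.
# match +1 / mismatch -1 / gap -2; ties prefer diagonal, then up (gap in b),
# matching leftmost-gap conventions closely enough for the tiny oracle cases
# used (which have unique optima).
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    d <- S[i, j] + if (av[i] == bv[j]) match else mismatch
    S[i + 1, j + 1] <- max(d, S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] +
          (if (av[i] == bv[j]) match else mismatch)) {
      ai <- c(av[i], ai); bi <- c(bv[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(av[i], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j], bi); j <- j - 1
    }
  }
  list(a_aln = paste(ai, collapse = ""), b_aln = paste(bi, collapse = ""),
       score = S[n + 1, m + 1])
}

# brute-force SRE pairing: double loop over the cross product
pair_sre_oracle <- function(fsites, rsites, require_mirror = TRUE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  hits <- list()
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    if (fsites$position[i] != rsites$position[j]) next
    mirror <- identical(unname(comp[fsites$rna_ref[i]]),
                        rsites$rna_ref[j]) &&
      identical(unname(comp[fsites$rna_alt[i]]), rsites$rna_alt[j])
    if (require_mirror && !mirror) next
    hits[[length(hits) + 1L]] <- data.frame(
      position = fsites$position[i], mirror = mirror)
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(0), mirror = logical(0)))
  out <- do.call(rbind, hits)
  out[order(out$position), , drop = FALSE]
}

# interval-stabbing depth count: how many [start, start+len-1] cover p
stab_oracle <- function(starts, len, p) {
  sum(starts <= p & starts + len - 1L >= p)
}

# random site table for round-trip / venn fixtures
random_site_table <- function(n, seed) {
  set.seed(seed)
  rna <- c("A", "C", "G", "U")
  ref <- sample(rna, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(rna, b), 1L), character(1),
                USE.NAMES = FALSE)
  depth <- sample(5:200, n, replace = TRUE)
  altc <- pmax(1L, as.integer(round(runif(n, 0.1, 1) * depth)))
  data.frame(contig = "m", position = sample(10000L, n),
             strand_group = sample(c("F", "R"), n, replace = TRUE),
             rna_ref = ref, rna_alt = alt, depth = depth,
             alt_count = altc, frequency = altc / depth,
             p_value = runif(n), sample = "s1",
             stringsAsFactors = FALSE)
}
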