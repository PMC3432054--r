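# Independent oracles, written against the algorithm definitions rather
# than the package implementation.

# Quadratic affine-gap Smith-Waterman (Gotoh), vectorized over subject
# columns within each query row. A gap of length L costs open + ext * L.
# Plus strand only; see swOracle() for the both-strand wrapper.
.swOracleOne <- function(query, subject, match = 2, mismatch = -3,
                         open = 5, ext = 2) {
  qv <- strsplit(query, "")[[1]]
  sv <- strsplit(subject, "")[[1]]
  m <- length(qv); n <- length(sv)
  Hprev <- numeric(n + 1)
  Fprev <- rep(-Inf, n + 1)
  best <- 0
  j <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- ifelse(sv == qv[i] & qv[i] != "N", match, mismatch)
    diag <- Hprev[j] + sub
    Fcur <- pmax(Hprev[j + 1] - open - ext, Fprev[j + 1] - ext)
    H0 <- pmax(0, diag, Fcur)
    # E (gap consuming subject) from H0 of the same row via running max:
    # E[j] = max_{k<j} (H0[k] - open - ext*(j-k))
    Ecur <- cummax(c(-Inf, H0[-n] + ext * (j[-n]))) - open - ext * j
    Hcur <- pmax(H0, Ecur)
    best <- max(best, max(Hcur))
    Hprev <- c(0, Hcur)
    Fprev <- c(-Inf, Fcur)
  }
  best
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

swOracle <- function(query, subject) {
  max(.swOracleOne(query, subject), .swOracleOne(revcomp(query), subject))
}

# Exhaustive 3'-suffix scan: longest suffix of the primer occurring at any
# position of any subject string, either strand, by direct comparison.
suffixOracle <- function(primer, subjects) {
  m <- nchar(primer)
  subjects <- c(subjects, vapply(subjects, revcomp, character(1)))
  for (len in m:1) {
    suf <- substr(primer, m - len + 1, m)
    if (any(vapply(subjects, function(s) grepl(suf, s, fixed = TRUE),
                   logical(1))))
      return(len)
  }
  0L
}

# Brute-force F2 gamete-table oracle for the repulsion-phase intercross:
# F1 carries haplotypes (M, +) and (+, a); returns the fraction of
# mutant-phenotype (a/a) F2 that carry the dominant marker M.
f2MutantMarkerOracle <- function(r) {
  gam <- data.frame(
    marker = c(TRUE, FALSE, TRUE, FALSE),
    mut    = c(FALSE, TRUE, TRUE, FALSE),
    p      = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  num <- 0; den <- 0
  for (i in 1:4) for (j in 1:4) {
    p <- gam$p[i] * gam$p[j]
    if (gam$mut[i] && gam$mut[j]) {
      den <- den + p
      if (gam$marker[i] || gam$marker[j]) num <- num + p
    }
  }
  num / den
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
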