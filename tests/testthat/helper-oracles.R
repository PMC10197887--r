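# Independent oracles, deliberately implemented differently from the
# package internals (string slicing + regex instead of vectorized
# classification; textbook formulas instead of library calls).

extdata <- function(f) system.file("extdata", f, package = "apobecscan")

oracle_chars <- function(genome_str) strsplit(genome_str, "")[[1]]

oracle_comp <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

# Channel of one SNV by direct slicing (NA when unclassifiable).
oracle_channel <- function(genome_str, pos, ref, alt) {
  ch <- oracle_chars(genome_str)
  if (pos < 2 || pos > length(ch) - 1) return(NA_character_)
  if (ch[pos] != ref) return(NA_character_)
  up <- ch[pos - 1]; dn <- ch[pos + 1]
  if (ref %in% c("A", "G")) {
    lab <- paste0(oracle_comp(dn), "[", oracle_comp(ref), ">",
                  oracle_comp(alt), "]", oracle_comp(up))
  } else {
    lab <- paste0(up, "[", ref, ">", alt, "]", dn)
  }
  if (grepl("N", lab)) NA_character_ else lab
}

# Overlap-aware TCW/WGA motif count in a window, by regex lookahead.
oracle_tcw_count <- function(w) {
  m <- gregexpr("(?=(TCA|TCT|TGA|AGA))", w, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Brute-force AMS for one sample on a single-contig genome.
oracle_ams <- function(genome_str, pos, ref, alt, window = 20) {
  ch <- oracle_chars(genome_str)
  L <- length(ch)
  nalt <- ifelse(ref == "G", oracle_comp(alt), alt)
  elig <- ref %in% c("C", "G") & nalt %in% c("T", "G")
  pos <- pos[elig]; ref <- ref[elig]
  n_mut_c <- length(pos)
  in_tcw <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    if (ref[i] == "C") {
      p > 1 && p < L && ch[p - 1] == "T" && ch[p + 1] %in% c("A", "T")
    } else {
      p > 1 && p < L && ch[p + 1] == "A" && ch[p - 1] %in% c("A", "T")
    }
  }, logical(1))
  wins <- vapply(pos, function(p)
    substr(genome_str, max(1, p - window), min(L, p + window)), character(1))
  n_ctx_tcw <- sum(vapply(wins, oracle_tcw_count, integer(1)))
  # C/G counted only at positions that could center an observable motif:
  # window edges and the two neighbors of the mutated base are excluded
  n_ctx_c <- sum(vapply(seq_along(wins), function(i) {
    v <- oracle_chars(wins[i])
    cen <- pos[i] - max(1, pos[i] - window) + 1
    drop <- unique(c(1, length(v), cen - 1, cen + 1))
    sum(v[-drop] %in% c("C", "G"))
  }, integer(1)))
  list(n_mut_tcw = sum(in_tcw), n_mut_c = n_mut_c,
       n_ctx_tcw = n_ctx_tcw, n_ctx_c = n_ctx_c,
       ams = (sum(in_tcw) / n_mut_c) / (n_ctx_tcw / n_ctx_c))
}

# Textbook step-up BH.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table
# (a b / c d), summing probabilities of all tables with the same margins
# whose probability does not exceed the observed (with fisher.test's
# relative tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Textbook two-group log-rank statistic from the risk table.
oracle_logrank_stat <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  dt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Tiny deterministic cohort used by several I/O tests.
toy_genome <- function() read_genome(extdata("toy_genome.fa"))
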