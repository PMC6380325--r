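# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain loops, no IRanges, a different genetic-code
# source where possible.

# gap partition of sorted positions: start a new block whenever the distance
# to the previous position exceeds `gap`
oracle_gap_partition <- function(pos, gap) {
  pos <- sort(pos)
  if (length(pos) == 0L) return(list())
  blocks <- list(pos[1])
  for (p in pos[-1]) {
    last <- blocks[[length(blocks)]]
    if (p - last[length(last)] <= gap) {
      blocks[[length(blocks)]] <- c(last, p)
    } else {
      blocks[[length(blocks) + 1L]] <- p
    }
  }
  blocks
}

# two-pass scan: enumerate maximal runs of ratio > run_thr, keep those whose
# maximum exceeds peak_thr; returns window index ranges
oracle_high_copy <- function(ratios, peak_thr = 2, run_thr = 1.25) {
  out <- list()
  i <- 1L
  n <- length(ratios)
  while (i <= n) {
    if (ratios[i] > run_thr) {
      j <- i
      while (j < n && ratios[j + 1L] > run_thr) j <- j + 1L
      if (any(ratios[i:j] > peak_thr)) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# hash-table k-mer counting: returns sorted start positions of k-mers seen
# more than once
oracle_kmer_repeats <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    env[[w]] <- c(if (!is.null(env[[w]])) env[[w]], i)
  }
  hits <- integer(0)
  for (w in ls(env)) if (length(env[[w]]) > 1L) hits <- c(hits, env[[w]])
  sort(hits)
}

# full-enumeration two-sided hypergeometric p for a 2x2 table, summing the
# probabilities of all tables no more likely than the observed one (the
# fisher.test convention, with its relative tolerance)
oracle_fisher_p <- function(tb) {
  m <- tb[1, 1] + tb[2, 1]
  n <- tb[1, 2] + tb[2, 2]
  k <- tb[1, 1] + tb[1, 2]
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= d[support == tb[1, 1]] * (1 + 1e-7)])
}

# ---- independent NG86 ------------------------------------------------------

.codon_aa <- local({
  # genetic code assembled from seqinr if available, else from Biostrings
  if (requireNamespace("seqinr", quietly = TRUE)) {
    bases <- c("T", "C", "A", "G")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1]]), "")
    setNames(aa, codons)
  } else {
    setNames(as.character(Biostrings::GENETIC_CODE),
             names(Biostrings::GENETIC_CODE))
  }
})

oracle_syn_sites <- function(codon) {
  aa <- .codon_aa[[codon]]
  if (aa == "*") return(NA_real_)
  s <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == b) next
      mut <- codon
      substr(mut, p, p) <- b
      if (.codon_aa[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# recursive enumeration of all orders of the differing positions
oracle_codon_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(0, 0))
  paths <- matrix(numeric(0), ncol = 3)  # sd, nd, valid
  recurse <- function(cur, remaining, sd, nd, valid) {
    if (length(remaining) == 0L) {
      paths <<- rbind(paths, c(sd, nd, valid))
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- .codon_aa[[cur]]
      a2 <- .codon_aa[[nxt]]
      recurse(nxt, setdiff(remaining, p),
              sd + (a1 == a2), nd + (a1 != a2),
              valid && a1 != "*" && a2 != "*")
    }
  }
  recurse(c1, pos, 0, 0, TRUE)
  use <- paths[, 3] == 1
  if (!any(use)) use <- rep(TRUE, nrow(paths))
  c(mean(paths[use, 1]), mean(paths[use, 2]))
}

oracle_ng86 <- function(seq1, seq2) {
  n <- nchar(seq1) %/% 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    c1 <- substr(seq1, 3 * i - 2, 3 * i)
    c2 <- substr(seq2, 3 * i - 2, 3 * i)
    s1 <- oracle_syn_sites(c1); s2 <- oracle_syn_sites(c2)
    if (is.na(s1) || is.na(s2)) next
    S <- S + (s1 + s2) / 2
    N <- N + 3 - (s1 + s2) / 2
    d <- oracle_codon_diff(c1, c2)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(s_sites = S, n_sites = N, s_diff = Sd, n_diff = Nd,
       ds = jc(Sd / S), dn = jc(Nd / N))
}

# ---- pileup construction helpers ------------------------------------------

# build pileup observation rows for one column from allele/count/qual/offset
# specs: list(list(base=, n=, qual=, off5=), ...)
pileup_column <- function(pos, alleles, genome = "g1", chrom = "ref",
                          read_len = 73L) {
  rows <- lapply(alleles, function(a) {
    qual <- if (is.null(a$qual)) 30L else a$qual
    off5 <- if (is.null(a$off5)) 30L else a$off5
    data.frame(genome_id = genome, chrom = chrom, pos = pos,
               base = a$base,
               qual = rep_len(qual, a$n),
               off5 = rep_len(off5, a$n),
               off3 = read_len - 1L - rep_len(off5, a$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

random_codon_pair <- function(max_div = 0.1) {
  # a random pair of 20 non-stop codons with sparse differences
  bases <- c("A", "C", "G", "T")
  draw_codon <- function() {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (.codon_aa[[cd]] != "*") return(cd)
    }
  }
  c1 <- replicate(20, draw_codon())
  c2 <- c1
  for (i in seq_along(c2)) {
    if (runif(1) < max_div * 3) {
      repeat {
        mut <- c2[i]
        p <- sample(3, 1)
        substr(mut, p, p) <- sample(bases, 1)
        if (.codon_aa[[mut]] != "*") { c2[i] <- mut; break }
      }
    }
  }
  c(paste(c1, collapse = ""), paste(c2, collapse = ""))
}
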