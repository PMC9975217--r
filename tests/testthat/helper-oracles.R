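# Independent oracles used to cross-check the pipeline implementation.
# They share no code with the package internals: the longest-common-
# substring oracle scans match runs along the diagonals of the character
# equality matrix, and components come from a hand-rolled union-find.

oracle_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n1 <- length(x); n2 <- length(y)
  best <- 0L
  for (k in (-(n1 - 1L)):(n2 - 1L)) {
    i <- max(1L, 1L - k); j <- max(1L, 1L + k)
    len <- min(n1 - i, n2 - j) + 1L
    eq <- x[i:(i + len - 1L)] == y[j:(j + len - 1L)]
    r <- rle(eq)
    hit <- r$lengths[r$values]
    if (length(hit) && max(hit) > best) best <- max(hit)
  }
  best
}

# edge rule applied literally, one pair at a time
oracle_edge <- function(seq_a, seq_b, short_a, short_b, min_cov = 0.8) {
  L <- oracle_lcs(seq_a, seq_b)
  cov_a <- L / nchar(seq_a)
  cov_b <- L / nchar(seq_b)
  if (xor(short_a, short_b)) {
    if (short_a) cov_a >= min_cov else cov_b >= min_cov
  } else {
    cov_a >= min_cov && cov_b >= min_cov
  }
}

oracle_union_find <- function(ids, edge_a, edge_b) {
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edge_a)) {
    ra <- find(match(edge_a[k], ids))
    rb <- find(match(edge_b[k], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(ids), find, 0L)
  split(ids, roots)
}

# brute-force pipeline: DP-free LCS oracle on all pairs + union-find
oracle_pipeline <- function(records, min_cov = 0.8, min_size = 6) {
  n <- nrow(records)
  sa <- records$short_amplicon
  if (is.null(sa)) sa <- rep(FALSE, n)
  ea <- character(0); eb <- character(0)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (oracle_edge(records$sequence[i], records$sequence[j],
                        sa[i], sa[j], min_cov)) {
          ea <- c(ea, records$id[i]); eb <- c(eb, records$id[j])
        }
      }
    }
  }
  comps <- oracle_union_find(records$id, ea, eb)
  comps <- comps[lengths(comps) >= min_size]
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1L))])
}

# random SSN instance mixing planted clusters, substring variants,
# mutated near-misses and unrelated singletons
random_ssn_instance <- function(n, len_range = c(40, 80),
                                p_short = 0.1) {
  bases <- c("A", "C", "G", "T")
  recs <- list()
  i <- 0L
  while (i < n) {
    size <- min(sample(1:6, 1L), n - i)
    L <- sample(len_range[1]:len_range[2], 1L)
    master <- paste(sample(bases, L, replace = TRUE), collapse = "")
    for (k in seq_len(size)) {
      kind <- sample(c("copy", "prefix", "mutant"), 1L,
                     prob = c(0.4, 0.4, 0.2))
      s <- switch(kind,
        copy = master,
        prefix = substr(master, 1L, sample(ceiling(0.7 * L):L, 1L)),
        mutant = {
          ch <- strsplit(master, "")[[1L]]
          pos <- sample(L, max(1L, round(L / 15)))
          ch[pos] <- vapply(ch[pos],
                            function(b) sample(setdiff(bases, b), 1L), "")
          paste(ch, collapse = "")
        })
      i <- i + 1L
      recs[[i]] <- data.frame(id = sprintf("s%03d", i), sequence = s,
                              short_amplicon = runif(1) < p_short,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

# classical periodogram of an evenly sampled series (FFT oracle)
oracle_even_periodogram <- function(x, dt = 1) {
  n <- length(x)
  xc <- x - mean(x)
  f <- seq_len(floor(n / 2)) / (n * dt)
  a <- abs(fft(xc))[2:(floor(n / 2) + 1L)]^2 / n
  list(freq = f, power = a)
}
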