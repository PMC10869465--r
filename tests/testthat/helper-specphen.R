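# Shared helpers and independent oracles for the test suite.

# Naive O(n^2) double-loop NDI oracle.
ndi_matrix_loop <- function(values) {
  n <- length(values)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- values[i] + values[j]
      m[i, j] <- if (s == 0) 0 else (values[i] - values[j]) / s
    }
  }
  m
}

# Pearson r from the raw covariance/variance definition (no cor()).
pearson_oracle_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-tailed p for Pearson r via the incomplete-beta closed form.
pearson_oracle_p <- function(r, n) {
  pbeta(1 - r^2, (n - 2) / 2, 1 / 2)
}

# Closed-form induction trace: phi(t) = A (1 - 2^(-t/tau)), NPQ given
# directly; back-computes F / Fm' from the PAM equations with fm = 4.
make_trace <- function(times, phi, npq_t, f0_frac = 0.19, fm = 4,
                       id = "s1") {
  fm_prime <- fm / (1 + npq_t)
  tibble::tibble(
    sample_id = id, time_s = times,
    f = fm_prime * (1 - phi), fm_prime = fm_prime,
    f0 = f0_frac * fm, fm = fm
  )
}

# ---- brute-force compact-letter-display oracle --------------------------
# For a symmetric significance matrix on n <= 6 groups: the letters must
# realise the non-significance relation exactly, with the minimum possible
# number of letters. A letter is a clique of the non-significance (NS)
# graph; a valid display is a set of NS cliques covering every vertex and
# every NS edge; the oracle finds the minimum cover size by exhaustive
# search over maximal cliques.

# all maximal cliques of an adjacency matrix (logical, symmetric), as
# vertex-index vectors
maximal_cliques_bf <- function(adj) {
  n <- nrow(adj)
  subsets <- lapply(seq_len(2^n) - 1L, function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
  })
  is_clique <- function(s) {
    if (length(s) < 2L) return(TRUE)
    all(adj[t(combn(s, 2L))])
  }
  cliques <- Filter(is_clique, subsets[-1L])
  keep <- vapply(cliques, function(a) {
    !any(vapply(cliques, function(b)
      length(b) > length(a) && all(a %in% b), TRUE))
  }, TRUE)
  cliques[keep]
}

# minimum number of NS cliques covering all vertices and NS edges
min_clique_cover_size <- function(sig) {
  n <- nrow(sig)
  ns <- !sig
  diag(ns) <- TRUE
  cliques <- maximal_cliques_bf(ns)
  edges <- which(ns & upper.tri(ns), arr.ind = TRUE)
  covers <- function(chosen) {
    verts_ok <- all(seq_len(n) %in% unlist(chosen))
    edges_ok <- nrow(edges) == 0L || all(apply(edges, 1L, function(e) {
      any(vapply(chosen, function(cl) all(e %in% cl), TRUE))
    }))
    verts_ok && edges_ok
  }
  for (k in seq_along(cliques)) {
    for (idx in utils::combn(length(cliques), k, simplify = FALSE)) {
      if (covers(cliques[idx])) return(k)
    }
  }
  length(cliques)
}

# significance matrix from an integer edge mask over the upper triangle
sig_from_mask <- function(n, mask) {
  sig <- matrix(FALSE, n, n, dimnames = list(paste0("g", 1:n),
                                             paste0("g", 1:n)))
  pairs <- which(upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L) {
      sig[pairs[k, 1L], pairs[k, 2L]] <- TRUE
      sig[pairs[k, 2L], pairs[k, 1L]] <- TRUE
    }
  }
  sig
}

# does a letter vector realise the sharing relation of `sig` exactly?
letters_match_sig <- function(letters_vec, sig) {
  n <- length(letters_vec)
  sets <- strsplit(letters_vec, "")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shares <- length(intersect(sets[[i]], sets[[j]])) > 0L
      if (shares == sig[i, j]) return(FALSE) # share iff NOT significant
    }
  }
  TRUE
}
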