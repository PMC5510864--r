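# Small deterministic toy world shared across tests: 1 x 200 kb chromosome
# pair, 6 genes with >= 4 exons of >= 250 bp (so adjacent junctions are
# genomically disjoint), one gap per chromosome.
toy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- make_genome(seed = 42L, n_chrom = 2L, chrom_len = 2e5L,
                         n_gaps = 1L, gap_len = 2000L)
      ann <- make_annotation(gen$genome, gen$gaps, n_genes = 6L,
                             exons_per_gene = 4:6,
                             exon_len = c(250L, 320L), seed = 42L)
      cache <<- list(genome = gen$genome, gaps = gen$gaps,
                     genes = ann$genes, features = ann$features)
    }
    cache
  }
})

# Independent average-linkage oracle: recompute all pairwise cluster
# distances from scratch at every step (no linkage update formula).
brute_average_linkage <- function(positions, cutoff) {
  cl <- lapply(sort(as.numeric(positions)), function(p) p)
  repeat {
    if (length(cl) < 2L) break
    best <- c(Inf, NA, NA)
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i >= j) next
      d <- mean(abs(outer(cl[[i]], cl[[j]], "-")))
      if (d < best[1]) best <- c(d, i, j)
    }
    if (best[1] > cutoff) break
    cl[[best[2]]] <- sort(c(cl[[best[2]]], cl[[best[3]]]))
    cl <- cl[-best[3]]
  }
  cl[order(vapply(cl, min, numeric(1)))]
}

# DKW sup-distance of p-values from Uniform(0,1)
dkw_stat <- function(p) {
  n <- length(p)
  max(abs(stats::ecdf(p)(sort(p)) - sort(p)))
}
dkw_band <- function(n, alpha = 1e-3) sqrt(log(2 / alpha) / (2 * n))
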