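#' Build the retroduplication carrier-frequency matrix
#'
#' For M unique parent genes and N populations, entry (m, n) is the fraction
#' of individuals of population n carrying at least one novel
#' retroduplication of gene m.
#'
#' @param calls `data.frame` of per-individual parent-gene calls with
#'   columns `gene_id` and `sample_id` (extra columns ignored).
#' @param manifest `data.frame` with one row per cohort individual:
#'   `sample_id`, `population`, and optionally `superpop`.
#' @return A `frequency_matrix` object: list with `freq` and `counts`
#'   (M x N matrices), `pop_sizes` (named integer vector) and `superpop`
#'   (named character vector mapping population to superpopulation, when
#'   the manifest provides one).
#' @export
build_frequency_matrix <- function(calls, manifest) {
  pops <- sort(unique(manifest$population))
  pop_sizes <- vapply(pops, function(p)
    length(unique(manifest$sample_id[manifest$population == p])), integer(1))
  genes <- sort(unique(calls$gene_id))
  counts <- matrix(0L, length(genes), length(pops),
                   dimnames = list(genes, pops))
  if (nrow(calls) > 0L) {
    calls$population <- manifest$population[match(calls$sample_id,
                                                  manifest$sample_id)]
    u <- unique(calls[, c("gene_id", "sample_id", "population")])
    tab <- table(factor(u$gene_id, levels = genes),
                 factor(u$population, levels = pops))
    counts[] <- as.integer(tab)
  }
  freq <- sweep(counts, 2L, pop_sizes, "/")
  superpop <- NULL
  if ("superpop" %in% names(manifest)) {
    superpop <- vapply(pops, function(p)
      manifest$superpop[match(p, manifest$population)], character(1))
  }
  structure(list(freq = freq, counts = counts, pop_sizes = pop_sizes,
                 superpop = superpop),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("Retroduplication frequency matrix: %d gene(s) x %d population(s), %d individuals\n",
              nrow(x$freq), ncol(x$freq), sum(x$pop_sizes)))
  invisible(x)
}

#' Fixation index of a carrier frequency across superpopulations
#'
#' \deqn{F_{ST} = \frac{p(1-p) - \sum_i c_i p_i (1-p_i)}{p(1-p)}}
#' where `p_i` is the carrier frequency in superpopulation i, `c_i` its
#' relative size, and `p = sum(c_i p_i)` the total-population frequency. By
#' concavity of p(1-p) the value lies in [0, 1]; when p is 0 or 1 there is
#' no variation and 0 is returned.
#'
#' @param p_by_superpop Carrier frequency per superpopulation.
#' @param c_by_superpop Relative superpopulation sizes (must sum to 1).
#' @return The fixation index in [0, 1].
#' @export
fst <- function(p_by_superpop, c_by_superpop) {
  stopifnot(length(p_by_superpop) == length(c_by_superpop),
            abs(sum(c_by_superpop) - 1) < 1e-8)
  p <- sum(c_by_superpop * p_by_superpop)
  denom <- p * (1 - p)
  if (denom <= 0) return(0)
  val <- (denom - sum(c_by_superpop * p_by_superpop * (1 - p_by_superpop))) / denom
  min(1, max(0, val))
}

#' Permutation test for superpopulation differentiation
#'
#' For each gene, the observed fixation index is compared against a null
#' distribution built by shuffling individual labels across the whole cohort
#' while keeping every population's size unchanged (rows of the carrier
#' matrix are permuted). One-tailed empirical p-values use the
#' `(r + 1) / (n + 1)` correction and are adjusted across genes by
#' Benjamini-Hochberg.
#'
#' @param carriers Logical/0-1 matrix, individuals x genes.
#' @param superpop Character vector: superpopulation of each individual
#'   (row of `carriers`).
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Optional RNG seed.
#' @return `data.frame`: `gene_id`, `fst`, `p_empirical`, `p_adjusted`.
#' @export
fst_permutation_test <- function(carriers, superpop, n_perm = 1000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  carriers <- as.matrix(carriers) * 1
  sp <- factor(superpop)
  n <- nrow(carriers)
  stopifnot(length(superpop) == n)
  ind <- stats::model.matrix(~ sp - 1)        # n x 5 indicator
  sizes <- colSums(ind)
  cvec <- sizes / n
  fst_all <- function(cm) {
    pmat <- t(t(crossprod(cm, ind)) / sizes)   # genes x superpops
    p <- as.vector(pmat %*% cvec)
    denom <- p * (1 - p)
    within <- as.vector((pmat * (1 - pmat)) %*% cvec)
    out <- ifelse(denom > 0, (denom - within) / denom, 0)
    pmin(pmax(out, 0), 1)
  }
  obs <- fst_all(carriers)
  exceed <- integer(ncol(carriers))
  for (b in seq_len(n_perm)) {
    perm <- fst_all(carriers[sample.int(n), , drop = FALSE])
    exceed <- exceed + (perm >= obs)
  }
  p_emp <- (exceed + 1) / (n_perm + 1)
  data.frame(gene_id = colnames(carriers) %||% paste0("g", seq_along(obs)),
             fst = obs,
             p_empirical = p_emp,
             p_adjusted = stats::p.adjust(p_emp, method = "BH"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Manhattan distances between population frequency profiles
#'
#' @param fm A `frequency_matrix` or a plain genes x populations matrix.
#' @return A symmetric `dist`-convertible matrix of Manhattan distances
#'   between population columns.
#' @export
manhattan_distances <- function(fm) {
  m <- if (methods::is(fm, "frequency_matrix")) fm$freq else as.matrix(fm)
  d <- as.matrix(stats::dist(t(m), method = "manhattan"))
  # snap away floating-point summation noise so that genuinely tied
  # distances stay tied regardless of gene row order
  signif(d, 12)
}

#' Average-linkage population tree
#'
#' Hierarchical clustering (average linkage) of the Manhattan distance
#' matrix between population frequency profiles.
#'
#' @inheritParams manhattan_distances
#' @return A `retro_tree` object: list with `hclust`, `phylo`
#'   (`ape::as.phylo`), and `clusters` (the leaf set below each internal
#'   node, used for bootstrap support).
#' @export
average_linkage_tree <- function(fm) {
  d <- stats::as.dist(manhattan_distances(fm))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 clusters = hclust_clusters(hc)),
            class = "retro_tree")
}

# Leaf-label sets of all internal nodes of an hclust tree, sorted within.
hclust_clusters <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) hc$labels[-k] else members[[k]]
    members[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  members
}

#' @export
print.retro_tree <- function(x, ...) {
  cat(sprintf("Population tree (%d leaves, average linkage / Manhattan)\n",
              length(x$hclust$labels)))
  if (!is.null(x$bp))
    cat(sprintf("  bootstrap support on %d internal edges (min %.2f, max %.2f)\n",
                length(x$bp), min(x$bp), max(x$bp)))
  invisible(x)
}

#' @export
plot.retro_tree <- function(x, support = c("bp", "au", "none"), ...) {
  support <- match.arg(support)
  ph <- x$phylo
  plot(ph, ...)
  lab <- switch(support, bp = x$bp, au = x$au, none = NULL)
  if (!is.null(lab))
    ape::nodelabels(sprintf("%.0f", 100 * lab), frame = "none", cex = 0.7)
  invisible(x)
}

#' Ordinary bootstrap support (BP) for population-tree clusters
#'
#' Gene rows of the frequency matrix are resampled with replacement; BP of a
#' cluster (an internal edge of the point-estimate tree, identified by its
#' leaf set) is the fraction of replicate trees containing the same leaf
#' bipartition.
#'
#' @inheritParams manhattan_distances
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @return The `retro_tree` with a `bp` vector (one value per internal
#'   node, in `clusters` order).
#' @export
bootstrap_support <- function(fm, n_boot = 1000, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  m <- if (methods::is(fm, "frequency_matrix")) fm$freq else as.matrix(fm)
  tree <- average_linkage_tree(m)
  keys <- vapply(tree$clusters, paste, character(1), collapse = "|")
  hits <- numeric(length(keys))
  M <- nrow(m)
  for (b in seq_len(n_boot)) {
    bm <- m[sample.int(M, M, replace = TRUE), , drop = FALSE]
    bt <- stats::hclust(stats::as.dist(manhattan_distances(bm)),
                        method = "average")
    bkeys <- vapply(hclust_clusters(bt), paste, character(1), collapse = "|")
    hits <- hits + (keys %in% bkeys)
  }
  tree$bp <- hits / n_boot
  tree
}

#' Approximately unbiased (AU) support from multiscale bootstrap
#'
#' Bootstrap resampling is repeated at several scale ratios rho (replicate
#' size `ceiling(rho * M)` gene rows). For each cluster the normal quantile
#' `z(rho) = qnorm(1 - BP(rho))` is fit to `v * sqrt(rho) + c / sqrt(rho)`
#' by weighted least squares (weights `n_boot * dnorm(z)^2 / (BP (1-BP))`),
#' and `AU = 1 - pnorm(v - c)`. Clusters with degenerate BP (0 or 1) at more
#' than half the scales are reported at their plain BP value with a warning.
#'
#' @inheritParams bootstrap_support
#' @param scales Scale ratios (default ten values from 0.5 to 1.4).
#' @param n_boot_per_scale Replicates per scale (default 1000).
#' @return The `retro_tree` with `bp` (at rho = 1) and `au` vectors.
#' @export
au_support <- function(fm, scales = seq(0.5, 1.4, by = 0.1),
                       n_boot_per_scale = 1000, seed = NULL) {
  if (n_boot_per_scale < 1) stop("n_boot_per_scale must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  m <- if (methods::is(fm, "frequency_matrix")) fm$freq else as.matrix(fm)
  tree <- average_linkage_tree(m)
  keys <- vapply(tree$clusters, paste, character(1), collapse = "|")
  M <- nrow(m)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, sprintf("rho=%.2f", scales)))
  for (si in seq_along(scales)) {
    Mb <- max(2L, ceiling(scales[si] * M))
    hits <- numeric(length(keys))
    for (b in seq_len(n_boot_per_scale)) {
      bm <- m[sample.int(M, Mb, replace = TRUE), , drop = FALSE]
      bt <- stats::hclust(stats::as.dist(manhattan_distances(bm)),
                          method = "average")
      hits <- hits + (keys %in% vapply(hclust_clusters(bt), paste,
                                       character(1), collapse = "|"))
    }
    bp[, si] <- hits / n_boot_per_scale
  }
  au <- numeric(length(keys))
  degenerate <- logical(length(keys))
  for (k in seq_len(length(keys))) {
    bpk <- bp[k, ]
    ok <- bpk > 0 & bpk < 1
    if (sum(ok) < length(scales) / 2) {
      degenerate[k] <- TRUE
      au[k] <- mean(bpk)           # clamp to the (degenerate) BP level
      next
    }
    z <- stats::qnorm(1 - bpk[ok])
    rho <- scales[ok]
    X <- cbind(sqrt(rho), 1 / sqrt(rho))
    w <- n_boot_per_scale * stats::dnorm(z)^2 / (bpk[ok] * (1 - bpk[ok]))
    fit <- stats::lm.wfit(X, z, w)
    v <- fit$coefficients[1]; cc <- fit$coefficients[2]
    au[k] <- 1 - stats::pnorm(v - cc)
  }
  if (any(degenerate))
    warning(sprintf("%d cluster(s) had degenerate BP at most scales; AU clamped to BP",
                    sum(degenerate)))
  rho1 <- which.min(abs(scales - 1))
  tree$bp <- bp[, rho1]
  tree$bp_by_scale <- bp
  tree$au <- pmin(pmax(au, 0), 1)
  tree
}

#' Fit the multiscale-bootstrap signed-distance model to a BP profile
#'
#' Exposed for testing parameter recovery: given BP values at several
#' scales, recover the signed distance `v` and curvature `c` of the
#' boundary, and the implied AU value.
#'
#' @param bp_by_scale BP values per scale.
#' @param scales Matching scale ratios.
#' @param n_boot Replicates per scale used to form the weights.
#' @return List with `v`, `c`, `au`.
#' @export
fit_au_model <- function(bp_by_scale, scales, n_boot = 1000) {
  ok <- bp_by_scale > 0 & bp_by_scale < 1
  stopifnot(sum(ok) >= 2)
  z <- stats::qnorm(1 - bp_by_scale[ok])
  rho <- scales[ok]
  X <- cbind(sqrt(rho), 1 / sqrt(rho))
  w <- n_boot * stats::dnorm(z)^2 / (bp_by_scale[ok] * (1 - bp_by_scale[ok]))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1]); cc <- unname(fit$coefficients[2])
  list(v = v, c = cc, au = 1 - stats::pnorm(v - cc))
}

#' Fraction of parent genes private to one superpopulation
#'
#' @param fm A `frequency_matrix`.
#' @param superpop_map Named character vector population -> superpopulation;
#'   defaults to the matrix's own `superpop` mapping.
#' @return Fraction of genes with nonzero carrier frequency in exactly one
#'   superpopulation (genes absent everywhere are excluded from the
#'   denominator).
#' @export
private_superpop_fraction <- function(fm, superpop_map = NULL) {
  superpop_map <- superpop_map %||% fm$superpop
  if (is.null(superpop_map)) stop("no superpopulation mapping available")
  sp <- superpop_map[colnames(fm$freq)]
  n_sp <- vapply(split(seq_len(ncol(fm$freq)), sp), function(cols)
    rowSums(fm$freq[, cols, drop = FALSE]) > 0, logical(nrow(fm$freq)))
  n_sp <- if (is.matrix(n_sp)) rowSums(n_sp) else sum(n_sp)
  present <- n_sp > 0
  if (!any(present)) return(0)
  mean(n_sp[present] == 1)
}
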