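# Independent oracles and fixture builders. These deliberately use different
# algorithms/code paths than the package implementations they check.

# Naive network-expansion oracle: repeated full passes over the reaction list
# until no pass adds a metabolite.
oracle_scope <- function(network, seeds) {
  avail <- unique(as.character(seeds))
  repeat {
    added <- FALSE
    for (r in network$reactions) {
      if (all(names(r$substrates) %in% avail) &&
          !all(names(r$products) %in% avail)) {
        avail <- union(avail, names(r$products))
        added <- TRUE
      }
      if (r$reversible && all(names(r$products) %in% avail) &&
          !all(names(r$substrates) %in% avail)) {
        avail <- union(avail, names(r$substrates))
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(avail)
}

# Random toy network, independent of the holobiont generator.
random_toy_network <- function(n_reactions, n_metabolites = 25, seed = 1) {
  set.seed(seed)
  mets <- paste0("m", seq_len(n_metabolites))
  rxns <- lapply(seq_len(n_reactions), function(i) {
    subs <- sample(mets, sample(1:3, 1))
    prods <- sample(setdiff(mets, subs), sample(1:2, 1))
    reaction(sprintf("r%d_%d", seed, i),
             stats::setNames(rep(1, length(subs)), subs),
             stats::setNames(rep(1, length(prods)), prods),
             reversible = stats::runif(1) < 0.3)
  })
  metabolic_network(paste0("rand", seed), rxns)
}

# Exhaustive O(n^3) UPGMA: returns the cophenetic distance matrix implied by
# average linkage over the original distances.
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Joint-ML NB oracle for a two-group Wald test: numerical optimisation of the
# full likelihood over (intercept, group effect, log dispersion), Wald p from
# the expected information at the optimum.
oracle_nb_wald <- function(y, group, offset = rep(0, length(y))) {
  x <- as.numeric(group)
  nll <- function(par) {
    mu <- exp(par[1] + par[2] * x + offset)
    a <- exp(par[3])
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  fit <- stats::optim(c(log(mean(y) + 0.5), 0, log(0.2)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  beta <- fit$par
  mu <- exp(beta[1] + beta[2] * x + offset)
  a <- exp(beta[3])
  X <- cbind(1, x)
  W <- mu / (1 + a * mu)
  se <- sqrt(solve(t(X * W) %*% X)[2, 2])
  list(log2fc = beta[2] / log(2), alpha = a,
       p = 2 * stats::pnorm(-abs(beta[2] / se)))
}

# Structural equality of two networks (id-keyed, order-free).
expect_network_equal <- function(a, b) {
  expect_setequal(names(a$reactions), names(b$reactions))
  expect_setequal(a$metabolites$id, b$metabolites$id)
  for (rid in names(a$reactions)) {
    ra <- a$reactions[[rid]]
    rb <- b$reactions[[rid]]
    expect_equal(ra$substrates[order(names(ra$substrates))],
                 rb$substrates[order(names(rb$substrates))])
    expect_equal(ra$products[order(names(ra$products))],
                 rb$products[order(names(rb$products))])
    expect_identical(ra$reversible, rb$reversible)
    expect_setequal(ra$genes, rb$genes)
    expect_setequal(ra$pathways, rb$pathways)
  }
}

# Two-condition design (one community, two salinities) used in calibration
# simulations.
one_community_design <- function(replicates = 4L) {
  make_design(communities = "MC1", replicates = replicates)
}
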