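# Independent oracles and fixture builders. Nothing here calls the
# package's solvers: the LP oracle enumerates basic solutions from first
# principles, the clustering oracle implements average-linkage
# agglomeration directly from its definition.

BIGB <- 1e6

# Brute-force bounded LP: optimize c'v s.t. S v = 0, l <= v <= u by
# enumerating candidate vertices (subsets of variables fixed at a bound,
# remaining square system solved). Exponential; for toys only.
brute_lp <- function(obj, S, lower, upper, sense = "max", tol = 1e-7,
                     all_optima = FALSE) {
  n <- length(obj)
  lower <- pmax(lower, -BIGB)
  upper <- pmin(upper, BIGB)
  S <- matrix(S, ncol = n)
  r <- qr(S)$rank
  k <- n - r
  best <- NULL
  best_val <- if (sense == "max") -Inf else Inf
  vertices <- list()
  fix_sets <- utils::combn(n, k, simplify = FALSE)
  if (k == 0) fix_sets <- list(integer(0))
  for (fx in fix_sets) {
    free <- setdiff(seq_len(n), fx)
    Sb <- S[, free, drop = FALSE]
    if (qr(Sb)$rank < r) next
    grid <- expand.grid(rep(list(c(1, 2)), length(fx)))
    if (!nrow(grid)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(fx)) {
        choice <- as.integer(grid[g, ])
        v[fx] <- ifelse(choice == 1, lower[fx], upper[fx])
      }
      rhs <- -S[, fx, drop = FALSE] %*% v[fx]
      sol <- tryCatch(qr.solve(Sb, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[free] <- sol
      if (any(v < lower - 1e-6) || any(v > upper + 1e-6)) next
      if (max(abs(S %*% v)) > 1e-6) next
      val <- sum(obj * v)
      vertices[[length(vertices) + 1L]] <- list(v = v, val = val)
      better <- if (sense == "max") val > best_val + tol else
        val < best_val - tol
      if (better) { best_val <- val; best <- v }
    }
  }
  if (is.null(best)) return(list(status = "infeasible"))
  out <- list(status = "optimal", objval = best_val, x = best)
  if (all_optima) {
    out$optima <- Filter(function(z) abs(z$val - best_val) <= 1e-6 * max(1, abs(best_val)),
                         vertices)
  }
  out
}

# Brute-force GIMME oracle: minimize sum(w |v|) s.t. S v = 0, bounds,
# biomass >= floor. Built here from first principles via the split
# formulation + brute_lp.
brute_gimme <- function(model, w, floor_value) {
  S <- stoichiometric_matrix(model)
  lb <- pmax(model$reactions$lower_bound, -BIGB)
  ub <- pmin(model$reactions$upper_bound, BIGB)
  obj <- model$reactions$objective_coefficient
  n <- length(w)
  rev_idx <- which(lb < 0)
  nb <- length(rev_idx)
  # vars: p (n), q (nb), s (surplus)
  A <- rbind(cbind(S, -S[, rev_idx, drop = FALSE], 0),
             c(obj, -obj[rev_idx], -1))
  lo <- c(pmax(lb, 0), rep(0, nb), 0)
  hi <- c(ub, -lb[rev_idx], BIGB)
  cost <- c(w, w[rev_idx], 0)
  # brute_lp assumes a homogeneous system (A x = 0); the biomass floor has
  # a nonzero rhs, carried by an auxiliary variable t fixed at 1:
  # obj'v - s - floor*t = 0  with t == 1  <=>  obj'v >= floor.
  A2 <- cbind(A, c(rep(0, nrow(S)), -floor_value))
  lo2 <- c(lo, 1)
  hi2 <- c(hi, 1)
  cost2 <- c(cost, 0)
  res <- brute_lp(cost2, A2, lo2, hi2, sense = "min")
  if (res$status != "optimal") return(res)
  v <- res$x[seq_len(n)]
  v[rev_idx] <- v[rev_idx] - res$x[n + seq_len(nb)]
  list(status = "optimal", penalty = res$objval, fluxes = v)
}

# Average-linkage agglomeration oracle on distance 1 - Pearson r, merging
# while the smallest average inter-cluster distance stays below `height`.
brute_average_linkage <- function(profiles, height = 0.5) {
  n <- nrow(profiles)
  D <- 1 - stats::cor(t(profiles))
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (best_d >= height) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  stats::setNames(memb, rownames(profiles))
}

# Label-invariant partition signature.
partition_signature <- function(memb) {
  groups <- split(sort(names(memb)), memb[sort(names(memb))])
  unname(sort(vapply(groups, paste, character(1), collapse = "|")))
}

# Quantile oracle: independent sort-and-interpolate implementation of the
# type-7 convention.
quantile_oracle <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ---- fixture builders ---------------------------------------------------

toy1 <- function() generate_toy_gem(1, "minimal")

# Small model builder from a compact reaction spec list.
make_model <- function(id, rxns, compartment = c(c = "cytosol")) {
  tab <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id, name = r$id,
               reversible = isTRUE(r$rev),
               lower_bound = if (!is.null(r$lb)) r$lb else if (isTRUE(r$rev)) -Inf else 0,
               upper_bound = if (!is.null(r$ub)) r$ub else Inf,
               subsystem = if (!is.null(r$sub)) r$sub else "",
               gene_association = if (!is.null(r$gpr)) r$gpr else "",
               objective_coefficient = if (!is.null(r$obj)) r$obj else 0,
               stringsAsFactors = FALSE)
  }))
  sto <- lapply(rxns, `[[`, "sto")
  names(sto) <- tab$id
  mets <- unique(unlist(lapply(sto, names)))
  metabolic_model(id,
                  data.frame(id = mets, name = mets,
                             compartment = names(compartment)[1],
                             external_id = NA_character_,
                             stringsAsFactors = FALSE),
                  tab, sto, compartment)
}

# Seeded random linear-pathway toys (<= 10 reactions): one bounded uptake,
# branched conversion chains, biomass drain. Always feasible and bounded.
random_toy <- function(seed) {
  set.seed(seed)
  n_mid <- sample(2:4, 1)
  mets <- c("M1", paste0("M", 1 + seq_len(n_mid)))
  rxns <- list(list(id = "UP", sto = c(M1 = 1), ub = round(stats::runif(1, 4, 12), 1)))
  for (i in seq_len(n_mid)) {
    from <- mets[i]; to <- mets[i + 1]
    coef <- sample(1:2, 1)
    sto <- stats::setNames(c(-1, coef), c(from, to))
    rxns[[length(rxns) + 1L]] <- list(id = paste0("C", i), sto = sto,
                                      rev = stats::runif(1) < 0.3)
    if (stats::runif(1) < 0.5) {   # parallel route
      rxns[[length(rxns) + 1L]] <- list(id = paste0("P", i),
                                        sto = stats::setNames(c(-1, 1), c(from, to)),
                                        ub = round(stats::runif(1, 1, 6), 1))
    }
  }
  last <- mets[length(mets)]
  rxns[[length(rxns) + 1L]] <- list(id = "BIO",
                                    sto = stats::setNames(-1, last),
                                    obj = 1)
  make_model(paste0("rand", seed), rxns)
}
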