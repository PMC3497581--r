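# Shared helpers: angular error, tiny in-code fixtures.

# absolute angular difference on the circle, degrees in [0, 180]
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# minimal valid sample table
make_samples <- function(specimen_id, species, genus, site, d13C, d15N) {
  df <- data.frame(specimen_id = specimen_id, species = species, genus = genus,
                   site = site, d13C = d13C, d15N = d15N,
                   stringsAsFactors = FALSE)
  class(df) <- c("isotope_samples", "data.frame")
  df
}

# samples placed at exact polar offsets from a known centroid, one genus
polar_samples <- function(angles_deg, magnitudes, genus = "G", site = "s1",
                          centroid = c(-28, 9), prefix = "id") {
  th <- angles_deg * pi / 180
  make_samples(
    specimen_id = paste0(prefix, seq_along(angles_deg)),
    species = paste0(genus, " sp"),
    genus = genus, site = site,
    d13C = centroid[1] + magnitudes * cos(th),
    d15N = centroid[2] + magnitudes * sin(th)
  )
}

# write a CSV sample file and return its path
write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random bifurcating tree with positive lengths (for oracle comparisons)
random_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 3)
  tr
}

# brute-force minimizer of the branch-length-weighted squared-change
# objective; independent oracle for pls_ancestral_states()
pls_oracle <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  tv <- if (!is.null(names(tip_values))) tip_values[tree$tip.label] else tip_values
  ntot <- ntip + tree$Nnode
  obj <- function(internal) {
    all_v <- c(unname(tv), internal)
    sum((all_v[tree$edge[, 1]] - all_v[tree$edge[, 2]])^2 / tree$edge.length)
  }
  grad <- function(internal) {
    all_v <- c(unname(tv), internal)
    d <- 2 * (all_v[tree$edge[, 1]] - all_v[tree$edge[, 2]]) / tree$edge.length
    g <- numeric(ntot)
    for (e in seq_along(d)) {
      g[tree$edge[e, 1]] <- g[tree$edge[e, 1]] + d[e]
      g[tree$edge[e, 2]] <- g[tree$edge[e, 2]] - d[e]
    }
    g[(ntip + 1):ntot]
  }
  fit <- stats::optim(rep(mean(tv), tree$Nnode), obj, grad, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))
  # polish by exact coordinate descent: the objective is quadratic in each
  # coordinate, so the vertex of the interpolating parabola through three
  # slice evaluations is the exact 1-D minimum (Brent-style optimize() is
  # limited to ~sqrt(eps) accuracy and cannot reach 1e-8 here)
  par <- fit$par
  h <- 0.5
  for (sweep in 1:2000) {
    delta <- 0
    for (j in seq_along(par)) {
      p <- par
      f0 <- obj(p)
      p[j] <- par[j] - h; fm <- obj(p)
      p[j] <- par[j] + h; fp <- obj(p)
      denom <- fp - 2 * f0 + fm
      if (denom > 0) {
        z <- par[j] - 0.5 * h * (fp - fm) / denom
        delta <- max(delta, abs(z - par[j]))
        par[j] <- z
      }
    }
    if (delta < 1e-13) break
  }
  c(unname(tv), par)
}
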