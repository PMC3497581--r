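# Ancestral niche-vector reconstruction on a phylogeny.
#
# Tip genera carry a mean vector (mu, r). The vector is projected onto
# independent Cartesian components X = r cos(mu) + 1, Y = r sin(mu) + 1
# (the +1 shift keeps all inputs positive, and is provably neutral for the
# estimator below). Each component is then reconstructed over internal
# nodes by minimizing the branch-length-weighted sum of squared changes
#
#     sum over branches (x_parent - x_child)^2 / branch_length,
#
# i.e. squared-change parsimony weighted by branch length — the exact
# least-squares / maximum-likelihood point reconstruction under Brownian
# motion. The minimizer solves a small sparse linear system; no iteration.

#' Read a Newick tree, enforcing positive branch lengths
#'
#' Parses a Newick file via \pkg{ape}. Trees without branch lengths get
#' unit lengths everywhere; individual missing, zero or negative lengths
#' are replaced by 1 (the weighted reconstruction divides by branch length,
#' so zero-length branches are not admissible). Replacement counts are
#' messaged.
#'
#' @param path path to a Newick file.
#' @return an \pkg{ape} `phylo` object with all edge lengths > 0.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_newick(): file not found: %s", path), call. = FALSE)
  }
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) {
    stop(sprintf("read_newick(): malformed Newick in %s: %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (is.null(tree)) {
    stop(sprintf("read_newick(): malformed Newick in %s", path), call. = FALSE)
  }
  ensure_branch_lengths(tree)
}

#' Replace missing/zero branch lengths by 1
#'
#' @param tree a `phylo` object.
#' @return the tree with strictly positive edge lengths.
#' @export
ensure_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    message(sprintf("no branch lengths: all %d set to 1", nrow(tree$edge)))
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  bad <- !is.finite(tree$edge.length) | tree$edge.length <= 0
  if (any(bad)) {
    message(sprintf("%d non-positive/missing branch length(s) set to 1", sum(bad)))
    tree$edge.length[bad] <- 1
  }
  tree
}

#' Prune a tree to a set of tip labels
#'
#' Minimal induced subtree on the requested tips; degree-2 internal nodes
#' left behind are collapsed with their branch lengths summed, so pairwise
#' path lengths among kept tips are conserved. Requested labels absent from
#' the tree are reported in a warning.
#'
#' @param tree a `phylo` object.
#' @param labels tip labels to keep (>= 2 must match).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, labels) {
  miss <- setdiff(labels, tree$tip.label)
  if (length(miss)) {
    warning(sprintf("prune_to_taxa(): label(s) not in tree: %s",
                    paste(miss, collapse = ", ")), call. = FALSE)
  }
  keep <- intersect(tree$tip.label, labels)
  if (length(keep) < 2) {
    stop("prune_to_taxa(): need at least 2 matching tips", call. = FALSE)
  }
  ape::keep.tip(tree, keep)
}

#' Collapse species-level tips to one tip per genus
#'
#' For trees whose tips are `Genus_species` (or `Genus species`) labels:
#' keeps one representative per genus — the configured type species if it
#' is present, else the first encountered — drops the rest, and relabels
#' the kept tip with the bare genus name.
#'
#' @param tree a `phylo` object with species-level tips.
#' @param type_species optional character vector of preferred
#'   representative tip labels (full species labels).
#' @return the genus-level `phylo` object.
#' @export
collapse_to_genera <- function(tree, type_species = NULL) {
  genus_of <- sub("[_ ].*$", "", tree$tip.label)
  keep <- vapply(unique(genus_of), function(g) {
    cand <- tree$tip.label[genus_of == g]
    pref <- intersect(type_species, cand)
    if (length(pref)) pref[1] else cand[1]
  }, character(1))
  out <- ape::keep.tip(tree, unname(keep))
  out$tip.label <- sub("[_ ].*$", "", out$tip.label)
  out
}

#' Project genus mean vectors to shifted Cartesian tip states
#'
#' `X = r cos(mu) + 1`, `Y = r sin(mu) + 1`, with mu in degrees. Since
#' group-level `r` lies in `[0, 1]`, X and Y lie in `[0, 2]`.
#'
#' @param summaries data.frame with columns `genus`, `mu_deg`, `r` (e.g.
#'   from [genus_individual_summary()] or [genus_site_summary()]).
#' @param shift additive positivity shift (default 1).
#' @return data.frame with `genus`, `X`, `Y`.
#' @export
tips_to_cartesian <- function(summaries, shift = 1) {
  if (any(is.na(summaries$mu_deg))) {
    stop("tips_to_cartesian(): undefined mean direction for: ",
         paste(summaries$genus[is.na(summaries$mu_deg)], collapse = ", "),
         call. = FALSE)
  }
  th <- deg2rad(summaries$mu_deg)
  data.frame(genus = summaries$genus,
             X = summaries$r * cos(th) + shift,
             Y = summaries$r * sin(th) + shift,
             stringsAsFactors = FALSE)
}

#' Branch-length-weighted least-squares ancestral states
#'
#' Exact minimizer of `sum((x_parent - x_child)^2 / length)` over internal
#' node values, with tip values fixed: the normal equations form a weighted
#' graph-Laplacian system over internal nodes, solved directly. Equals
#' unweighted squared-change parsimony when all branch lengths are equal,
#' and the Brownian-motion least-squares reconstruction in general.
#'
#' @param tree a `phylo` object with positive branch lengths.
#' @param tip_values numeric vector of one character's tip states, named by
#'   tip label (or unnamed in `tree$tip.label` order).
#' @return numeric vector of states for all nodes, in ape node numbering
#'   (tips `1..n`, then internals); tip entries echo the input.
#' @export
pls_ancestral_states <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("pls_ancestral_states(): tree must have positive branch lengths",
         call. = FALSE)
  }
  if (!is.null(names(tip_values))) {
    miss <- setdiff(tree$tip.label, names(tip_values))
    if (length(miss)) {
      stop("pls_ancestral_states(): missing tip value(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tip_values <- tip_values[tree$tip.label]
  } else if (length(tip_values) != ntip) {
    stop("pls_ancestral_states(): need one value per tip", call. = FALSE)
  }
  if (!all(is.finite(tip_values))) {
    stop("pls_ancestral_states(): non-finite tip values", call. = FALSE)
  }
  A <- matrix(0, nint, nint)
  b <- numeric(nint)
  w <- 1 / tree$edge.length
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - ntip  # parents are always internal
    ch <- tree$edge[e, 2]
    A[p, p] <- A[p, p] + w[e]
    if (ch > ntip) {
      c2 <- ch - ntip
      A[c2, c2] <- A[c2, c2] + w[e]
      A[p, c2] <- A[p, c2] - w[e]
      A[c2, p] <- A[c2, p] - w[e]
    } else {
      b[p] <- b[p] + w[e] * tip_values[ch]
    }
  }
  x <- tryCatch(solve(A, b), error = function(e) {
    stop("pls_ancestral_states(): singular system (degenerate tree)",
         call. = FALSE)
  })
  out <- c(unname(tip_values), x)
  names(out) <- c(tree$tip.label, (ntip + 1):(ntip + nint))
  out
}

#' Convert shifted Cartesian node states back to angles and sectors
#'
#' Un-shifts (`X - shift`, `Y - shift`), recovers the direction with full
#' quadrant correction (`atan2`, mapped to `[0, 360)`), bins it into eight
#' half-open 45-degree sectors `floor(angle/45)`, and labels each node's
#' position on both isotope axes from the component signs. A node exactly
#' at the shifted origin has no direction (`NA` angle/sector).
#'
#' @param X,Y numeric vectors of shifted node states.
#' @param shift the positivity shift used on the way in (default 1).
#' @return data.frame with `X`, `Y`, `angle_deg`, `sector`, `N_label`
#'   (`"15N-enriched"` / `"15N-depleted"` / `"centroid"`), `C_label`
#'   (`"13C-enriched"` / `"13C-depleted"` / `"centroid"`).
#' @export
states_to_angles <- function(X, Y, shift = 1) {
  dx <- X - shift
  dy <- Y - shift
  ang <- vector_angle(dx, dy)
  data.frame(
    X = X, Y = Y,
    angle_deg = ang,
    sector = ifelse(is.na(ang), NA_integer_, as.integer(floor(ang / 45))),
    N_label = ifelse(dy > 0, "15N-enriched",
                     ifelse(dy < 0, "15N-depleted", "centroid")),
    C_label = ifelse(dx > 0, "13C-enriched",
                     ifelse(dx < 0, "13C-depleted", "centroid")),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct ancestral niche vectors for a set of genus summaries
#'
#' End-to-end wrapper: matches summaries to tree tips (pruning the tree to
#' summarized genera, or erroring, per `prune`), projects tips to shifted
#' Cartesian states, reconstructs X and Y independently by
#' [pls_ancestral_states()], and derives per-node angles, 45-degree
#' sectors and axis labels.
#'
#' @param tree a `phylo` object whose tips are genus labels.
#' @param summaries data.frame with `genus`, `mu_deg`, `r`.
#' @param prune drop tips without summaries (default `TRUE`); if `FALSE`,
#'   unmatched tips are an error listing the orphans.
#' @param unit_lengths if `TRUE`, rerun with every branch length set to 1
#'   (the "no branch lengths" analysis variant).
#' @return list with `tree` (as used), and `states`: a data.frame with
#'   `node`, `parent` (`NA` at the root), `label`, `is_tip`, `X`, `Y`,
#'   `angle_deg`, `sector`, `N_label`, `C_label`.
#' @export
ancestral_vector_states <- function(tree, summaries, prune = TRUE,
                                    unit_lengths = FALSE) {
  have <- intersect(tree$tip.label, summaries$genus)
  orphan_tips <- setdiff(tree$tip.label, summaries$genus)
  if (length(orphan_tips)) {
    if (!prune) {
      stop("ancestral_vector_states(): tips without summaries: ",
           paste(orphan_tips, collapse = ", "), call. = FALSE)
    }
    tree <- prune_to_taxa(tree, have)
  }
  extra <- setdiff(summaries$genus, tree$tip.label)
  if (length(extra)) {
    message(sprintf("ancestral_vector_states(): %d summarized genus(era) not in tree: %s",
                    length(extra), paste(extra, collapse = ", ")))
  }
  if (unit_lengths) tree$edge.length <- rep(1, nrow(tree$edge))
  tree <- ensure_branch_lengths(tree)
  cart <- tips_to_cartesian(summaries[summaries$genus %in% tree$tip.label, ,
                                      drop = FALSE])
  xs <- pls_ancestral_states(tree, stats::setNames(cart$X, cart$genus))
  ys <- pls_ancestral_states(tree, stats::setNames(cart$Y, cart$genus))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  geo <- states_to_angles(unname(xs), unname(ys))
  states <- cbind(
    data.frame(node = seq_len(nn), parent = parent,
               label = c(tree$tip.label, paste0("node", (ntip + 1):nn)),
               is_tip = seq_len(nn) <= ntip, stringsAsFactors = FALSE),
    geo
  )
  list(tree = tree, states = states)
}

#' Count label transitions along branches of one isotope axis
#'
#' A transition is a branch whose endpoints carry different axis labels
#' (e.g. 15N-enriched parent, 15N-depleted child). Branches with an
#' undefined or `"centroid"` endpoint are skipped and counted separately.
#'
#' @param tree the `phylo` object the states were computed on.
#' @param states the `states` data.frame from [ancestral_vector_states()].
#' @param axis `"N"` (d15N sign, from Y) or `"C"` (d13C sign, from X).
#' @return list with `transitions`, `skipped`, and `branches` (data.frame
#'   of the transition branches).
#' @export
count_axis_transitions <- function(tree, states, axis = c("N", "C")) {
  axis <- match.arg(axis)
  lab <- if (axis == "N") states$N_label else states$C_label
  defined <- !is.na(lab) & lab != "centroid"
  p <- tree$edge[, 1]
  ch <- tree$edge[, 2]
  usable <- defined[p] & defined[ch]
  trans <- usable & (lab[p] != lab[ch])
  list(
    transitions = sum(trans),
    skipped = sum(!usable),
    branches = data.frame(parent = p[trans], child = ch[trans],
                          from = lab[p][trans], to = lab[ch][trans],
                          stringsAsFactors = FALSE)
  )
}

#' Default 8-color palette for 45-degree sectors
#'
#' One color per half-open sector `[k*45, (k+1)*45)`, k = 0..7.
#'
#' @return named character vector of 8 hex colors.
#' @export
sector_palette <- function() {
  stats::setNames(
    c("#D73027", "#FC8D59", "#FEE090", "#FFFFBF",
      "#E0F3F8", "#91BFDB", "#4575B4", "#762A83"),
    paste0("sector", 0:7)
  )
}

#' Write reconstructed node states as TSV
#'
#' @param states the `states` data.frame from [ancestral_vector_states()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_states <- function(states, path) {
  utils::write.table(states, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}
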