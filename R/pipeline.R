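# Genus-level analysis partitions and publication-shaped reports.
#
# Two partitions of the individual vectors are summarized:
#   1. individual-based — all individual angles pooled by genus across
#      sites (sensitive to uneven sampling across sites);
#   2. genus-by-site — individuals first collapsed to one mean vector per
#      (genus, site) cell, then the cell *angles* summarized per genus
#      (each site contributes equally).
# Group-level circular statistics always operate on angles only (unit
# vectors): per-individual per-mil magnitudes are reported but never enter
# the circular summaries, which keeps all Cartesian projections of group
# means inside [-1, 1].

.drop_undefined <- function(vectors) {
  und <- is.na(vectors$angle_deg)
  if (any(und)) {
    warning(sprintf("%d zero-magnitude vector(s) excluded from circular statistics",
                    sum(und)), call. = FALSE)
  }
  vectors[!und, , drop = FALSE]
}

.summary_row <- function(genus, angles, min_n_rao, rao_method, rao_seed) {
  s <- circ_summary(angles, min_n_rao = min_n_rao, rao_method = rao_method,
                    rao_seed = rao_seed)
  data.frame(
    genus = genus, n = s$n, mu_deg = s$mu_deg, r = s$r, kappa = s$kappa,
    circ_variance = s$circ_variance, circ_sd_deg = s$circ_sd_deg,
    rayleigh_Z = s$rayleigh_Z, rayleigh_P = s$rayleigh_P,
    rao_U = s$rao_U, rao_P_lower = s$rao_P_lower, rao_P_upper = s$rao_P_upper,
    rao_label = s$rao_label, stringsAsFactors = FALSE
  )
}

#' Individual-based circular summary per genus
#'
#' Pools every individual vector of a genus across sites and computes the
#' full circular summary block, plus the number of individuals and of
#' assemblages (sites) sampled. Zero-magnitude vectors are excluded with a
#' warning; a genus with no defined direction at all is dropped.
#'
#' @param vectors output of [individual_vectors()].
#' @param min_n_rao minimum n for Rao's spacing test (default 4; smaller
#'   groups print `"-"`).
#' @param rao_method,rao_seed passed to [circ_summary()].
#' @return data.frame, one row per genus: `genus`, `n_individuals`,
#'   `n_assemblages`, and the circular summary columns.
#' @export
genus_individual_summary <- function(vectors, min_n_rao = 4L,
                                     rao_method = "table", rao_seed = 1L) {
  v <- .drop_undefined(vectors)
  if (nrow(v) == 0L) stop("no defined vectors to summarize", call. = FALSE)
  dropped <- setdiff(unique(vectors$genus), unique(v$genus))
  if (length(dropped)) {
    warning(sprintf("genus with only zero-magnitude vectors excluded: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(sort(unique(v$genus)), function(g) {
    vg <- v[v$genus == g, , drop = FALSE]
    row <- .summary_row(g, vg$angle_deg, min_n_rao, rao_method, rao_seed)
    cbind(data.frame(genus = g, n_individuals = nrow(vg),
                     n_assemblages = length(unique(vg$site)),
                     stringsAsFactors = FALSE),
          row[, setdiff(names(row), c("genus", "n"))])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean vector per (genus, site) cell
#'
#' Collapses the individuals of each genus at each site to a single mean
#' vector via [circular_mean()] on their angles. The cell's `r` is the mean
#' resultant length of its individual unit vectors.
#'
#' @param vectors output of [individual_vectors()].
#' @return data.frame with `genus`, `site`, `mu_deg`, `r`, `n` — one row
#'   per non-empty (genus, site) cell with at least one defined direction.
#' @export
genus_site_means <- function(vectors) {
  v <- .drop_undefined(vectors)
  key <- interaction(v$genus, v$site, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(v)), key), function(i) {
    m <- circular_mean(v$angle_deg[i])
    data.frame(genus = v$genus[i[1]], site = v$site[i[1]],
               mu_deg = m$mu_deg, r = m$r, n = m$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genus-by-site circular summary per genus
#'
#' Summarizes each genus over its per-site mean *angles* (one angle per
#' occupied site; the per-site `r` is deliberately discarded — sites enter
#' as unit vectors so every site counts equally). A genus present at a
#' single site is a singleton sample: `r = 1`, Rayleigh P = 0.512,
#' concentration undefined.
#'
#' @param site_means output of [genus_site_means()].
#' @param min_n_rao,rao_method,rao_seed as in [genus_individual_summary()].
#' @return data.frame, one row per genus: `genus`, `n_assemblages`, and the
#'   circular summary columns.
#' @export
genus_site_summary <- function(site_means, min_n_rao = 4L,
                               rao_method = "table", rao_seed = 1L) {
  sm <- site_means[!is.na(site_means$mu_deg), , drop = FALSE]
  if (nrow(sm) == 0L) stop("no defined site mean vectors", call. = FALSE)
  rows <- lapply(sort(unique(sm$genus)), function(g) {
    ang <- sm$mu_deg[sm$genus == g]
    row <- .summary_row(g, ang, min_n_rao, rao_method, rao_seed)
    cbind(data.frame(genus = g, n_assemblages = length(ang),
                     stringsAsFactors = FALSE),
          row[, setdiff(names(row), c("genus", "n"))])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Optionally split a genus into named species groups
#'
#' Rewrites the `genus` column so that listed species are treated as their
#' own operational taxonomic unit (e.g. splitting a morphologically
#' heterogeneous genus into two species groups before summarizing).
#'
#' @param vectors output of [individual_vectors()].
#' @param splits named list: `list("GroupLabel" = c("species a", "species b"))`.
#' @return the vector table with `genus` rewritten for the listed species.
#' @export
apply_genus_splits <- function(vectors, splits) {
  if (is.null(splits) || length(splits) == 0L) return(vectors)
  for (label in names(splits)) {
    vectors$genus[vectors$species %in% splits[[label]]] <- label
  }
  vectors
}

#' Direction/length vs species-richness association tests
#'
#' For each requested genus, tests whether its vector direction (circular)
#' or vector length (linear) co-varies with assemblage species richness —
#' the diagnostic for assemblage-size bias in centroid-standardized
#' vectors. Test 1 uses individual vectors (direction = individual angle,
#' length = individual per-mil magnitude); Test 2 uses genus-by-site mean
#' vectors (direction = site mean angle, length = site mean resultant `r`).
#'
#' @param vectors output of [individual_vectors()].
#' @param centroids output of [assemblage_centroids()] (provides richness).
#' @param genera genera to test; defaults to all.
#' @param min_n minimum paired observations per test (default 4); smaller
#'   groups are skipped with a message.
#' @return data.frame, one row per genus and test, with `genus`, `test`
#'   (`"individual"` or `"site_mean"`), `n`, `circ_R2`, `circ_P`, `lin_R2`,
#'   `lin_P`.
#' @export
richness_bias_tests <- function(vectors, centroids, genera = NULL, min_n = 4L) {
  v <- .drop_undefined(vectors)
  if (is.null(genera)) genera <- sort(unique(v$genus))
  rich <- stats::setNames(centroids$species_richness, centroids$site)
  sm <- genus_site_means(vectors)
  rows <- list()
  for (g in genera) {
    vg <- v[v$genus == g, , drop = FALSE]
    smg <- sm[sm$genus == g, , drop = FALSE]
    for (test in c("individual", "site_mean")) {
      if (test == "individual") {
        ang <- vg$angle_deg; len <- vg$magnitude; x <- unname(rich[vg$site])
      } else {
        ang <- smg$mu_deg; len <- smg$r; x <- unname(rich[smg$site])
      }
      if (length(ang) < min_n) {
        message(sprintf("richness_bias_tests(): %s/%s skipped (n = %d < %d)",
                        g, test, length(ang), min_n))
        next
      }
      cl <- circ_linear_correlation(ang, x, lengths = len)
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, test = test, n = cl$n,
        circ_R2 = cl$circ_R2, circ_P = cl$circ_P,
        lin_R2 = cl$lin_R2, lin_P = cl$lin_P,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(genus = character(), test = character(), n = integer(),
                      circ_R2 = numeric(), circ_P = numeric(),
                      lin_R2 = numeric(), lin_P = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- report formatting ------------------------------------------------------

#' Significance mark for a Rayleigh p-value
#'
#' `"*"` for P < 0.05, `"†"` (dagger) for 0.10 > P >= 0.05, otherwise
#' the empty string. No multiple-testing correction is applied.
#'
#' @param p numeric vector of p-values.
#' @return character vector of marks.
#' @export
significance_mark <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.05, "*", ifelse(p < 0.10, "†", "")))
}

.fmt_num <- function(x, digits, undef = "-") {
  ifelse(is.na(x) | is.infinite(x), undef,
         formatC(x, format = "f", digits = digits))
}

.fmt_deg <- function(x, undef = "-") {
  ifelse(is.na(x) | is.infinite(x), undef,
         sprintf("%d°", as.integer(round(x))))
}

.format_summary_block <- function(df) {
  # singleton groups (n=1): dispersion block undefined in print, as in
  # published tables ("-" for concentration/variance/SD at r = 1, n = 1)
  singleton <- if ("n_individuals" %in% names(df)) df$n_individuals == 1 else df$n_assemblages == 1
  kap <- df$kappa; vr <- df$circ_variance; sd <- df$circ_sd_deg
  vr[singleton] <- NA; sd[singleton] <- NA
  data.frame(
    mean_vector_mu = .fmt_deg(df$mu_deg),
    mean_vector_r = .fmt_num(df$r, 2),
    concentration = .fmt_num(kap, 2),
    circ_variance = .fmt_num(vr, 2),
    circ_sd = .fmt_deg(sd),
    rayleigh_P = .fmt_num(df$rayleigh_P, 3),
    rao_P = df$rao_label,
    stringsAsFactors = FALSE
  )
}

#' Write an individual-based genus summary table (TSV)
#'
#' Columns follow the individual-partition report layout: genus (with
#' significance mark), individuals, assemblages, mean vector direction,
#' mean vector length, concentration, circular variance, circular SD,
#' Rayleigh P, Rao P bracket. Angles print as integer degrees, `r` and
#' variance to 2 decimals, P to 3 decimals; undefined cells print `"-"`.
#'
#' @param summary output of [genus_individual_summary()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_individual <- function(summary, path) {
  out <- cbind(
    data.frame(genus = paste0(summary$genus, significance_mark(summary$rayleigh_P)),
               individuals = summary$n_individuals,
               assemblages = summary$n_assemblages,
               stringsAsFactors = FALSE),
    .format_summary_block(summary)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genus-by-site summary table (TSV)
#'
#' As [write_table_individual()] but for the genus-by-site partition (no
#' individuals column).
#'
#' @param summary output of [genus_site_summary()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_site <- function(summary, path) {
  out <- cbind(
    data.frame(genus = paste0(summary$genus, significance_mark(summary$rayleigh_P)),
               assemblages = summary$n_assemblages,
               stringsAsFactors = FALSE),
    .format_summary_block(summary)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write richness-association tests (TSV)
#'
#' @param tests output of [richness_bias_tests()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_richness <- function(tests, path) {
  out <- data.frame(
    genus = tests$genus, test = tests$test, n = tests$n,
    circ_R2 = .fmt_num(tests$circ_R2, 2),
    circ_P = .fmt_num(tests$circ_P, 3),
    lin_R2 = .fmt_num(tests$lin_R2, 2),
    lin_P = .fmt_num(tests$lin_P, 3),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
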