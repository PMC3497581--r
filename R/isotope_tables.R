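# Sample tables, species means, assemblage centroids and niche vectors.
#
# The standardization logic lives here: every specimen's (d13C, d15N) pair
# is re-expressed as a displacement from the centroid of its local
# assemblage, where the centroid is the *unweighted* mean of the per-species
# means at that site (species means first, so that heavily sampled species
# do not drag the centroid toward themselves).

.required_cols <- c("specimen_id", "species", "genus", "site", "d13C", "d15N")

#' Read a table of individual isotope samples
#'
#' Reads a delimited UTF-8 text file (CSV by default, TSV for `.tsv`/`.txt`
#' or `sep = "\t"`) with one specimen per row. Column names can be remapped
#' via `schema`, a named character vector `c(internal = "file_column")` for
#' any of `specimen_id`, `species`, `genus`, `site`, `d13C`, `d15N`.
#'
#' Rows with missing (blank or NA) isotope values are dropped with a message
#' reporting the count; a non-numeric isotope cell that is not blank is a
#' parse error naming the row. Duplicate specimen ids and species mapped to
#' more than one genus are structural errors.
#'
#' @param path path to the delimited file.
#' @param schema optional named character vector remapping column names.
#' @param sep field separator; inferred from the file extension if `NULL`.
#' @return data.frame of class `isotope_samples` with columns
#'   `specimen_id`, `species`, `genus`, `site`, `d13C`, `d15N`; the number
#'   of rejected rows is attached as attribute `n_rejected`.
#' @export
read_samples <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("read_samples(): file not found: %s", path), call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  colmap <- stats::setNames(.required_cols, .required_cols)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), .required_cols)
    if (length(bad)) {
      stop(sprintf("read_samples(): unknown schema keys: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    colmap[names(schema)] <- schema
  }
  missing_cols <- colmap[!(colmap %in% names(raw))]
  if (length(missing_cols)) {
    stop(sprintf("read_samples(): missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    specimen_id = trimws(raw[[colmap["specimen_id"]]]),
    species     = trimws(raw[[colmap["species"]]]),
    genus       = trimws(raw[[colmap["genus"]]]),
    site        = trimws(raw[[colmap["site"]]]),
    d13C        = trimws(raw[[colmap["d13C"]]]),
    d15N        = trimws(raw[[colmap["d15N"]]]),
    stringsAsFactors = FALSE
  )
  parse_iso <- function(x, col) {
    miss <- is.na(x) | x == "" | toupper(x) == "NA"
    val <- suppressWarnings(as.numeric(x))
    bad <- !miss & is.na(val)
    if (any(bad)) {
      stop(sprintf("read_samples(): non-numeric %s value '%s' at data row %d",
                   col, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
    }
    val
  }
  df$d13C <- parse_iso(df$d13C, "d13C")
  df$d15N <- parse_iso(df$d15N, "d15N")
  drop <- is.na(df$d13C) | is.na(df$d15N)
  if (any(drop)) {
    message(sprintf("read_samples(): rejected %d row(s) with missing isotope values",
                    sum(drop)))
    df <- df[!drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_samples(df)
  attr(df, "n_rejected") <- sum(drop)
  class(df) <- c("isotope_samples", "data.frame")
  df
}

#' Validate an isotope sample table
#'
#' Enforces the structural invariants: unique specimen ids, finite isotope
#' values, and a many-to-one species-to-genus mapping.
#'
#' @param samples data.frame with the `isotope_samples` columns.
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_samples <- function(samples) {
  need <- setdiff(.required_cols, names(samples))
  if (length(need)) {
    stop(sprintf("sample table lacks column(s): %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(samples$specimen_id)) {
    dups <- unique(samples$specimen_id[duplicated(samples$specimen_id)])
    stop(sprintf("duplicate specimen_id(s): %s",
                 paste(utils::head(dups, 5), collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(samples$d13C)) || !all(is.finite(samples$d15N))) {
    stop("non-finite isotope values in sample table", call. = FALSE)
  }
  g_per_sp <- tapply(samples$genus, samples$species, function(g) length(unique(g)))
  if (any(g_per_sp > 1)) {
    stop(sprintf("species mapped to more than one genus: %s",
                 paste(names(g_per_sp)[g_per_sp > 1], collapse = ", ")),
         call. = FALSE)
  }
  invisible(samples)
}

#' Per-species, per-site mean isotope signatures
#'
#' Arithmetic means of d13C and d15N over the individuals of each species at
#' each site. A species sampled at two sites contributes a separate mean to
#' each site (centroids are local-assemblage constructs).
#'
#' @param samples an `isotope_samples` table (or any data.frame with the
#'   same columns).
#' @return data.frame with `species`, `genus`, `site`, `mean_d13C`,
#'   `mean_d15N`, `n`, one row per (species, site) pair.
#' @export
species_means <- function(samples) {
  validate_samples(samples)
  if (nrow(samples) == 0L) stop("species_means(): empty sample table", call. = FALSE)
  key <- interaction(samples$species, samples$site, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(samples)), key)
  rows <- lapply(idx, function(i) {
    data.frame(
      species = samples$species[i[1]],
      genus = samples$genus[i[1]],
      site = samples$site[i[1]],
      mean_d13C = mean(samples$d13C[i]),
      mean_d15N = mean(samples$d15N[i]),
      n = length(i),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemblage centroid for one site
#'
#' The centroid is the unweighted arithmetic mean over the site's species
#' means — not over individuals — so that unequal sample sizes across
#' species do not bias it. Species richness is the number of distinct
#' species with at least one sample at the site.
#'
#' @param sp_means output of [species_means()].
#' @param site site label.
#' @return one-row data.frame with `site`, `c13`, `c15`, `species_richness`.
#' @export
assemblage_centroid <- function(sp_means, site) {
  rows <- sp_means[sp_means$site == site, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("assemblage_centroid(): unknown site '%s'", site), call. = FALSE)
  }
  data.frame(
    site = site,
    c13 = mean(rows$mean_d13C),
    c15 = mean(rows$mean_d15N),
    species_richness = length(unique(rows$species)),
    stringsAsFactors = FALSE
  )
}

#' Assemblage centroids for every site
#'
#' @param sp_means output of [species_means()].
#' @return data.frame with one row per site (see [assemblage_centroid()]).
#' @export
assemblage_centroids <- function(sp_means) {
  out <- do.call(rbind, lapply(sort(unique(sp_means$site)),
                               function(s) assemblage_centroid(sp_means, s)))
  rownames(out) <- NULL
  out
}

#' Centroid-standardized vectors for every individual
#'
#' For each specimen, the displacement from its site's assemblage centroid:
#' `dx = d13C - c13`, `dy = d15N - c15`, with direction `atan2(dy, dx)`
#' mapped to `[0, 360)` and Euclidean magnitude in per mil. A specimen lying
#' exactly on the centroid has zero magnitude and an undefined (`NA`)
#' direction.
#'
#' @param samples an `isotope_samples` table.
#' @param centroids output of [assemblage_centroids()]; every sampled site
#'   must be present.
#' @return data.frame of class `niche_vectors` with `owner`, `species`,
#'   `genus`, `site`, `dx`, `dy`, `angle_deg`, `magnitude`.
#' @export
individual_vectors <- function(samples, centroids) {
  validate_samples(samples)
  orphan <- setdiff(unique(samples$site), centroids$site)
  if (length(orphan)) {
    stop(sprintf("individual_vectors(): no centroid for site(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  i <- match(samples$site, centroids$site)
  dx <- samples$d13C - centroids$c13[i]
  dy <- samples$d15N - centroids$c15[i]
  out <- data.frame(
    owner = samples$specimen_id,
    species = samples$species,
    genus = samples$genus,
    site = samples$site,
    dx = dx,
    dy = dy,
    angle_deg = vector_angle(dx, dy),
    magnitude = sqrt(dx^2 + dy^2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("niche_vectors", "data.frame")
  out
}

#' Write a vector table as TSV
#'
#' @param vectors output of [individual_vectors()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vector_table <- function(vectors, path) {
  utils::write.table(
    vectors[, c("owner", "site", "dx", "dy", "angle_deg", "magnitude")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "-"
  )
  invisible(path)
}
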