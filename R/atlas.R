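#' The 77-region grey-matter atlas
#'
#' Returns the package's canonical atlas: the 77 cortical and subcortical
#' grey-matter volumes of interest (VOIs) of the Hammers adult
#' maximum-probability parcellation, together with the eight composite
#' regions (frontal, parietal, temporal, occipital, insula, limbic,
#' basal_ganglia, cerebellum) and default regional volumes used for
#' volume-weighted means. All regional analyses in this package are driven
#' by the region names and ordering defined here.
#'
#' @param path Optional path to an alternative atlas CSV with columns
#'   `label`, `name`, `composite`, `volume_mm3`. Defaults to the packaged
#'   file.
#' @return An object of class `dlb_atlas`: a list with `regions` (a tibble
#'   with columns `label`, `name`, `composite`, `volume_mm3`, one row per
#'   VOI in canonical order) and `composites` (a named list mapping each of
#'   the eight composite names to a character vector of member regions).
#' @examples
#' atlas <- hammers_atlas()
#' nrow(atlas$regions)        # 77
#' names(atlas$composites)    # the 8 composites
#' @export
hammers_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hammers77_gm_atlas.csv", package = "dlbnet")
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  regions <- tibble::as_tibble(raw)
  new_atlas(regions)
}

composite_names <- c(
  "frontal", "parietal", "temporal", "occipital",
  "insula", "limbic", "basal_ganglia", "cerebellum"
)

new_atlas <- function(regions) {
  stopifnot(all(c("label", "name", "composite", "volume_mm3") %in% names(regions)))
  if (nrow(regions) != 77L) {
    stop("atlas must define exactly 77 regions, got ", nrow(regions))
  }
  if (anyDuplicated(regions$name) || anyDuplicated(regions$label)) {
    stop("atlas region names and labels must be unique")
  }
  if (any(!is.finite(regions$volume_mm3)) || any(regions$volume_mm3 <= 0)) {
    stop("atlas volumes must be strictly positive")
  }
  bad <- setdiff(setdiff(unique(regions$composite), "none"), composite_names)
  if (length(bad)) stop("unknown composite(s): ", paste(bad, collapse = ", "))
  composites <- lapply(composite_names, function(cn) {
    regions$name[regions$composite == cn]
  })
  names(composites) <- composite_names
  if (any(lengths(composites) == 0L)) {
    stop("every composite must have at least one member region")
  }
  structure(
    list(regions = regions, composites = composites),
    class = "dlb_atlas"
  )
}

#' @export
print.dlb_atlas <- function(x, ...) {
  cat("<dlb_atlas> 77 grey-matter VOIs,", length(x$composites), "composites\n")
  sizes <- vapply(x$composites, length, integer(1))
  cat(paste0("  ", names(sizes), ": ", sizes, collapse = "\n"), "\n")
  invisible(x)
}

#' Region names of an atlas in canonical order
#'
#' @param atlas A `dlb_atlas`.
#' @return Character vector of the 77 region names.
#' @export
atlas_regions <- function(atlas) atlas$regions$name

#' Region volumes of an atlas in canonical order
#'
#' @param atlas A `dlb_atlas`.
#' @return Numeric vector of volumes (mm^3), named by region.
#' @export
atlas_volumes <- function(atlas) {
  stats::setNames(atlas$regions$volume_mm3, atlas$regions$name)
}

# internal: extract the subjects x 77 value matrix from a cohort tibble,
# columns in atlas order; errors on missing region columns.
cohort_values <- function(cohort, atlas) {
  regions <- atlas_regions(atlas)
  missing <- setdiff(regions, names(cohort))
  if (length(missing)) {
    stop("cohort table is missing region column(s): ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(cohort[, regions, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$subject_id
  m
}

cohort_groups <- c("HC", "DLB", "DLB_DATPOS", "DLB_DATNEG", "AD", "PD", "MSA")
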