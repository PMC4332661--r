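#' @keywords internal
#' Per-hemisphere cortical labels of the built-in bilateral atlas.
#'
#' The 34 thickness-bearing Desikan-Killiany labels of the FreeSurfer `aparc`
#' parcellation plus `corpuscallosum` (present in the annotation), giving the
#' conventional 35 labels per hemisphere / 70 bilateral regions used by this
#' package. Alphabetical; region order is a package convention, not an
#' anatomical claim.
dk_base_labels <- function() {
  sort(c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
    "corpuscallosum", "cuneus", "entorhinal", "frontalpole", "fusiform",
    "inferiorparietal", "inferiortemporal", "insula", "isthmuscingulate",
    "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "paracentral", "parahippocampal",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  ))
}

new_region_atlas <- function(region_names, hemisphere) {
  structure(
    list(region_names = region_names, hemisphere = hemisphere),
    class = "region_atlas"
  )
}

validate_region_atlas <- function(atlas) {
  rn <- atlas$region_names
  hemi <- atlas$hemisphere
  if (length(rn) != 70L) {
    stop("atlas must have exactly 70 regions, got ", length(rn), call. = FALSE)
  }
  if (anyDuplicated(rn)) {
    stop("duplicate region names in atlas: ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  }
  if (!all(hemi %in% c("lh", "rh"))) {
    stop("hemisphere tags must be 'lh' or 'rh'", call. = FALSE)
  }
  counts <- table(factor(hemi, levels = c("lh", "rh")))
  if (any(counts != 35L)) {
    stop("atlas must have exactly 35 regions per hemisphere (got lh=",
         counts[["lh"]], ", rh=", counts[["rh"]], ")", call. = FALSE)
  }
  invisible(atlas)
}

#' Load a bilateral cortical region atlas
#'
#' Defines the 70-region naming contract used throughout the package: 35
#' left-hemisphere plus 35 right-hemisphere Desikan-Killiany-style labels.
#' Region identifiers are of the form `"lh_bankssts"` / `"rh_temporalpole"`.
#' The built-in `"dk70"` atlas orders regions left hemisphere first,
#' alphabetically within hemisphere; a file-based atlas preserves file order.
#'
#' @param spec either the built-in atlas name `"dk70"` or the path to a text
#'   file with one region identifier (`lh_*` / `rh_*`) per line.
#' @return a `region_atlas` object with `region_names` (length 70, unique,
#'   canonical order) and per-region `hemisphere` tags.
#' @examples
#' atlas <- load_atlas("dk70")
#' length(atlas$region_names)  # 70
#' @export
load_atlas <- function(spec = "dk70") {
  if (identical(spec, "dk70")) {
    base <- dk_base_labels()
    atlas <- new_region_atlas(
      region_names = c(paste0("lh_", base), paste0("rh_", base)),
      hemisphere = rep(c("lh", "rh"), each = 35L)
    )
    return(validate_region_atlas(atlas))
  }
  if (!is.character(spec) || length(spec) != 1L) {
    stop("atlas spec must be a single atlas name or file path", call. = FALSE)
  }
  if (!file.exists(spec)) {
    stop("unknown atlas name or missing atlas file: '", spec, "'",
         call. = FALSE)
  }
  rn <- readLines(spec)
  rn <- trimws(rn)
  rn <- rn[nzchar(rn)]
  hemi <- substr(rn, 1L, 2L)
  if (!all(grepl("^(lh|rh)_", rn))) {
    bad <- rn[!grepl("^(lh|rh)_", rn)]
    stop("atlas file entries must be prefixed 'lh_' or 'rh_': ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  validate_region_atlas(new_region_atlas(rn, hemi))
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas: 70 regions (35 lh + 35 rh)\n")
  cat("  first:", x$region_names[1L], " last:", x$region_names[70L], "\n")
  invisible(x)
}

atlas_identical <- function(a, b) {
  identical(a$region_names, b$region_names)
}

# atlas argument flexibility: feature selection and pair counting also accept
# a bare character vector of region names (used by small-p test oracles)
region_names_of <- function(atlas) {
  if (inherits(atlas, "region_atlas")) return(atlas$region_names)
  if (is.character(atlas)) return(atlas)
  stop("atlas must be a region_atlas or a character vector", call. = FALSE)
}
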