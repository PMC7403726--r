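#' Construct a marker map
#'
#' An ordered panel of biallelic markers with physical positions on a single
#' reference sequence, together with the boundaries of the haplotype region
#' of interest.  Positions are treated as opaque increasing integers so that
#' any assembly's coordinates can be used.
#'
#' @param name character vector of unique marker names, in panel order.
#' @param position_bp integer vector of 1-based physical positions, strictly
#'   increasing in panel order.
#' @param kind marker type, `"snp"` or `"indel"` (recycled).
#' @param region_start_bp,region_end_bp integers delimiting the haplotype
#'   region; markers inside `[region_start_bp, region_end_bp]` (and not
#'   listed in `flanking_markers`) are the *region markers* used for
#'   haplotype classification.
#' @param flanking_markers optional names of markers to treat as outside the
#'   region regardless of position.
#'
#' @return An object of class `marker_map`: a data frame with columns
#'   `name`, `position_bp`, `kind` and attributes `region_start_bp`,
#'   `region_end_bp`, `flanking_markers`.
#' @export
marker_map <- function(name, position_bp, kind = "snp",
                       region_start_bp = min(position_bp),
                       region_end_bp = max(position_bp),
                       flanking_markers = character()) {
  name <- as.character(name)
  if (length(name) == 0L) stop("no markers")
  position_bp <- as.integer(position_bp)
  kind <- rep_len(as.character(kind), length(name))
  if (anyDuplicated(name)) {
    stop("duplicate marker name: ", name[duplicated(name)][1L])
  }
  if (any(is.na(position_bp)) || any(position_bp < 1L)) {
    stop("positions must be integers >= 1")
  }
  if (length(position_bp) != length(name)) {
    stop("name and position_bp lengths differ")
  }
  if (any(diff(position_bp) <= 0L)) {
    bad <- name[which(diff(position_bp) <= 0L)[1L] + 1L]
    stop("non-monotone positions at marker ", bad)
  }
  if (!all(kind %in% c("snp", "indel"))) stop("kind must be 'snp' or 'indel'")
  region_start_bp <- as.integer(region_start_bp)
  region_end_bp <- as.integer(region_end_bp)
  if (region_start_bp >= region_end_bp) {
    stop("region_start_bp must be < region_end_bp")
  }
  if (!all(flanking_markers %in% name)) {
    stop("flanking_markers not in panel: ",
         paste(setdiff(flanking_markers, name), collapse = ", "))
  }
  map <- data.frame(name = name, position_bp = position_bp, kind = kind,
                    stringsAsFactors = FALSE)
  attr(map, "region_start_bp") <- region_start_bp
  attr(map, "region_end_bp") <- region_end_bp
  attr(map, "flanking_markers") <- as.character(flanking_markers)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Read a marker map from a tab-separated file
#'
#' The file must have a header row with columns `name`, `position_bp` and
#' `kind`.  Region boundaries default to the span of the panel.
#'
#' @param path file path.
#' @inheritParams marker_map
#' @return A [marker_map].
#' @export
read_marker_map <- function(path, region_start_bp = NULL, region_end_bp = NULL,
                            flanking_markers = character()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("no markers in ", path)
  need <- c("name", "position_bp", "kind")
  if (!all(need %in% names(tab))) {
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  }
  marker_map(tab$name, as.integer(tab$position_bp), tab$kind,
             region_start_bp = region_start_bp %||% min(as.integer(tab$position_bp)),
             region_end_bp = region_end_bp %||% max(as.integer(tab$position_bp)),
             flanking_markers = flanking_markers)
}

#' Write a marker map to a tab-separated file
#' @param map a [marker_map].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Region markers of a map
#'
#' Names of the markers that lie inside the haplotype region and are not
#' declared flanking.  These are the markers used for carrier classification
#' and recombinant detection.
#'
#' @param map a [marker_map].
#' @return character vector of marker names, in panel order.
#' @export
region_markers <- function(map) {
  inside <- map$position_bp >= attr(map, "region_start_bp") &
    map$position_bp <= attr(map, "region_end_bp")
  map$name[inside & !(map$name %in% attr(map, "flanking_markers"))]
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers, region %d-%d bp\n", nrow(x),
              attr(x, "region_start_bp"), attr(x, "region_end_bp")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Default 17-marker panel across a 16-kb haplotype
#'
#' A synthetic stand-in for the genotyping panel used across the Eda
#' haplotype: 17 SNP and indel assays spanning 16 kb, anchored by named
#' markers in the field's nomenclature (Stn382 at the 5' intron-1 end, the
#' NAKA SNP 3' of the coding region, SNP13 near the 3' boundary).  Exact
#' assay positions are configurable; these defaults only preserve order and
#' approximate spacing.
#'
#' @param naka_marker name given to the NAKA SNP.
#' @return A [marker_map] of 17 markers.
#' @export
default_marker_map <- function(naka_marker = "NAKA") {
  marker_map(
    name = c("Stn382", "SNP2", "LP3621", "Cnv770", "SNP4", "SNP5",
             "Stn381", "SNP6", "SNP7", "LP13173", "SNP8", "SNP9",
             "SNP10", naka_marker, "SNP11", "SNP12", "SNP13"),
    position_bp = c(500L, 1500L, 2600L, 3100L, 4200L, 5400L, 6800L, 8000L,
                    9200L, 10100L, 11000L, 11900L, 12400L, 12800L, 13600L,
                    14700L, 15600L),
    kind = c("indel", "snp", "indel", "indel", "snp", "snp", "indel", "snp",
             "snp", "indel", "snp", "snp", "snp", "snp", "snp", "snp", "snp"),
    region_start_bp = 1L, region_end_bp = 16000L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
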