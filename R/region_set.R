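#' Region sets: the node sets of a covariance network
#'
#' A region set is an ordered list of unique region labels, optionally tagged
#' with a hemisphere, that defines the nodes of one covariance network. The
#' order is fixed at construction and preserved through every pipeline stage
#' (residualization, correlation, graph measures), so that row/column `i` of
#' any downstream matrix always refers to `regions[i]`.
#'
#' @param regions character vector of unique region labels (length >= 3;
#'   graph summary measures are not meaningful below three nodes).
#' @param name label for the network this set defines, e.g. `"global"` or
#'   `"thalamic"`.
#' @param hemisphere optional character vector, same length as `regions`,
#'   with entries `"lh"`, `"rh"` or `NA` for midline/unlateralized regions.
#' @return An object of class `region_set`.
#' @examples
#' rs <- region_set(c("A", "B", "C"), name = "toy")
#' length(rs$regions)
#' @export
region_set <- function(regions, name = "custom", hemisphere = NULL) {
  regions <- as.character(regions)
  if (length(regions) < 3L)
    stop("a region set needs at least 3 regions; got ", length(regions))
  if (anyDuplicated(regions))
    stop("duplicated region labels: ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  if (!is.null(hemisphere)) {
    if (length(hemisphere) != length(regions))
      stop("'hemisphere' must have one entry per region")
    bad <- !is.na(hemisphere) & !hemisphere %in% c("lh", "rh")
    if (any(bad)) stop("hemisphere entries must be 'lh', 'rh' or NA")
  }
  structure(list(name = as.character(name)[1],
                 regions = regions,
                 hemisphere = hemisphere),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set '", x$name, "': ", length(x$regions), " regions>\n", sep = "")
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$regions)

# Desikan-Killiany cortical parcel names (34 per hemisphere).
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

.subcortical <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
                  "Hippocampus", "Amygdala", "Accumbens")

# FreeSurfer-7 style thalamic nucleus labels (25 per hemisphere).
.thalamic_nuclei <- c(
  "AV", "CeM", "CL", "CM", "LD", "LGN", "LP", "L_Sg", "MDl", "MDm",
  "MGN", "MV_Re", "Pc", "Pf", "Pt", "PuA", "PuI", "PuL", "PuM",
  "VA", "VAmc", "VLa", "VLp", "VM", "VPL")

#' Built-in default region sets
#'
#' Two configurable default node sets: a `"global"` set of 82 regions
#' (68 Desikan-Killiany-style cortical parcels plus 14 subcortical
#' structures, both hemispheres) and a `"thalamic"` set of 50 thalamic
#' nuclei (25 FreeSurfer-7-style nucleus labels per hemisphere). These are
#' stand-ins for study-specific node lists: any analysis can substitute its
#' own labels via [region_set()].
#'
#' @param which `"global"` or `"thalamic"`.
#' @return A [region_set()].
#' @examples
#' length(default_region_set("global"))   # 82
#' length(default_region_set("thalamic")) # 50
#' @export
default_region_set <- function(which = c("global", "thalamic")) {
  which <- match.arg(which)
  if (which == "global") {
    labels <- c(paste0("lh_", .dk_cortical), paste0("rh_", .dk_cortical),
                paste0("Left-", .subcortical), paste0("Right-", .subcortical))
    hemi <- c(rep("lh", 34), rep("rh", 34), rep("lh", 7), rep("rh", 7))
  } else {
    labels <- c(paste0("Left-", .thalamic_nuclei),
                paste0("Right-", .thalamic_nuclei))
    hemi <- c(rep("lh", 25), rep("rh", 25))
  }
  region_set(labels, name = which, hemisphere = hemi)
}
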