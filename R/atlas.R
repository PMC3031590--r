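#' Cortical atlas table (66-region Desikan-Killiany parcellation)
#'
#' Returns the 66-region cortical parcellation used to label network nodes:
#' 33 anatomical regions per hemisphere. Region labels are the hemisphere
#' prefix plus the conventional abbreviation (e.g. `L.ST` = left superior
#' temporal).
#'
#' @return data.frame with columns `region` (unique label, e.g. `"L.BSTS"`),
#'   `hemisphere` (`"left"`/`"right"`), `abbreviation` and `name`.
#' @examples
#' atlas <- atlasTable()
#' table(atlas$hemisphere)
#' @export
atlasTable <- function() {
    path <- system.file("extdata", "atlas_dk66.tsv", package = "cortnet",
                        mustWork = TRUE)
    atlas <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(nrow(atlas) == 66L, !anyDuplicated(atlas$region))
    atlas
}

# Node labels for an arbitrary region count: the atlas for 66, generic
# zero-padded labels otherwise (the generator allows non-atlas sizes).
.regionLabels <- function(nRegions) {
    if (nRegions == 66L) atlasTable()$region
    else sprintf("R%03d", seq_len(nRegions))
}
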