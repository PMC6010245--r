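# Registry of the 100 collagen feature names.
#
# Naming scheme: No* = counts (per mm^2), Str{Area,Length,Width} = per-string
# means, leading region-less names = whole-tissue; suffix A = aggregated
# (cross-linked) strings only, D = distributed strings only. Region codes:
# CV = central vein, PT = portal tract, PS = perisinusoidal. The
# perisinusoidal distributed string-length feature is registered under its
# historical name "StrLengthSFD" (not "StrLengthPSD").

region_feature_names <- function(region) {
  counts <- c("NoStr", "NoShortStr", "NoLongStr", "NoThickStr", "NoThinStr")
  means <- c("StrArea", "StrLength", "StrWidth")
  nm <- c(
    region,                            # collagen % of region area
    paste0("Agg", region),             # aggregated collagen % of region area
    paste0("Dis", region),             # distributed collagen % of region area
    paste0("AggRatio", region),        # aggregated share of region collagen %
    paste0(counts, region),
    paste0(counts, region, "A"),
    paste0(counts, region, "D"),
    paste0(means, region),
    paste0(means, region, "A"),
    paste0(means, region, "D")
  )
  if (region == "PS") nm[nm == "StrLengthPSD"] <- "StrLengthSFD"
  nm
}

global_feature_names <- function() {
  c(
    "Col", "Agg", "Dis", "AggRatio",
    "NoStr", "NoShortStr", "NoLongStr", "NoThickStr", "NoThinStr",
    "NoStrA", "NoStrD",
    "StrArea", "StrLength", "StrWidth",
    "StrAreaA", "StrAreaD"
  )
}

#' Names of the 100 collagen features
#'
#' Returns the canonical ordered names of the collagen feature vector: 28
#' features for each of the central-vein (CV), portal-tract (PT) and
#' perisinusoidal (PS) regions, followed by 16 whole-tissue features.
#' Percentages (`CV`, `AggPT`, `Col`, ...) are collagen-pixel percentages of
#' the relevant area; `No*` features are string counts per square millimetre;
#' `Str{Area,Length,Width}*` are per-string means in square micrometres or
#' micrometres. Suffix `A` restricts to aggregated (cross-linked) strings,
#' `D` to distributed strings.
#'
#' @return Character vector of length 100.
#' @export
#' @examples
#' length(feature_names())
#' selected_feature_names() %in% feature_names()
feature_names <- function() {
  c(
    region_feature_names("CV"),
    region_feature_names("PT"),
    region_feature_names("PS"),
    global_feature_names()
  )
}

#' Names of the 14 selected B-index features
#'
#' The 14 collagen features retained by sequential forward selection for the
#' SHG B-index: the percentage of aggregated collagen (`Agg`), mean string
#' width (`StrWidth`), percentage of central-vein collagen (`CV`), and
#' region-specific string counts, areas and lengths.
#'
#' @return Character vector of length 14, a subset of [feature_names()].
#' @export
selected_feature_names <- function() {
  c(
    "Agg", "StrWidth", "CV", "NoThickStrCV", "StrAreaCV", "StrLengthCV",
    "StrLengthCVA", "StrAreaCVD", "NoThinStrPTA", "NoThickStrPTD",
    "NoStrPSD", "NoShortStrPSD", "StrAreaPSD", "StrLengthSFD"
  )
}

#' Feature-name registry as a JSON schema string
#'
#' @param path Optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
feature_schema_json <- function(path = NULL) {
  schema <- list(
    n_features = 100L,
    regions = list(CV = region_feature_names("CV"),
                   PT = region_feature_names("PT"),
                   PS = region_feature_names("PS")),
    global = global_feature_names(),
    selected = selected_feature_names()
  )
  json <- jsonlite::toJSON(schema, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
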