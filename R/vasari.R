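#' VASARI qualitative feature schema
#'
#' Declares the coded vocabulary consumed by the models: binary items (coded
#' by their positive category), the ordered edema-proportion item (reference
#' level `low`), morphology proportions collapsed to `low`/`high`, nominal
#' location items, and continuous size measurements in mm.
#'
#' @return A list of per-feature declarations (`name`, `type`, `levels`,
#'   `positive`), of class `gx_vasari_schema`.
#' @export
vasari_schema <- function() {
  bin <- function(name, positive = "yes", levels = c("no", "yes"))
    list(name = name, type = "binary", levels = levels, positive = positive)
  structure(list(
    bin("eloquent_cortex"),
    bin("multifocality"),
    bin("subependymal_extension"),
    list(name = "edema_proportion", type = "ordinal",
         levels = c("low", "medium", "high")),
    bin("t1_flair_ratio", positive = "increased",
        levels = c("not_increased", "increased")),
    list(name = "major_axis_mm", type = "numeric"),
    list(name = "minor_axis_mm", type = "numeric"),
    list(name = "location", type = "nominal",
         levels = c("frontal", "temporal", "parietal", "occipital")),
    list(name = "tumor_side", type = "nominal", levels = c("left", "right")),
    list(name = "proportion_necrosis", type = "ordinal",
         levels = c("low", "high")),
    list(name = "proportion_nonenhancing", type = "ordinal",
         levels = c("low", "high")),
    bin("thickness_enhancing_margin", positive = "thick",
        levels = c("thin", "thick")),
    bin("definition_enhancing_margin", positive = "poorly_defined",
        levels = c("well_defined", "poorly_defined")),
    bin("hemorrhage"),
    bin("pial_invasion"),
    bin("deep_wm_invasion"),
    bin("midline_cross")),
    class = "gx_vasari_schema")
}

#' Default recoding map for raw VASARI categories
#'
#' Collapses the raw multi-categorical scores into the coded groups of
#' [vasari_schema()] at clinically natural cut-points (e.g. edema proportion
#' `none` and `less_than_third` both code as `low`, the reference level).
#' The map is data, not code: it round-trips through JSON and a user-supplied
#' map with the same structure is accepted anywhere this default is.
#'
#' @return Named list: feature -> named character vector raw -> coded.
#' @export
default_recoding_map <- function() {
  prop3 <- c(none = "low", less_than_third = "low",
             third_to_two_thirds = "medium", over_two_thirds = "high")
  prop2 <- c(none = "low", less_than_third = "low",
             third_to_two_thirds = "high", over_two_thirds = "high")
  list(edema_proportion = prop3,
       proportion_necrosis = prop2,
       proportion_nonenhancing = prop2)
}

#' Recode a raw VASARI table into the coded schema
#'
#' Applies the recoding map column-wise; coded values are fixed points, so
#' the operation is idempotent. Unknown raw categories become missing and are
#' counted in the `"recode_log"` attribute; a missing schema column is a
#' schema error.
#'
#' @param raw data frame, one row per patient, with a `patient_id` column and
#'   one column per schema feature.
#' @param map recoding map as from [default_recoding_map()].
#' @param schema a [vasari_schema()].
#' @return Recoded data frame with attribute `"recode_log"`.
#' @export
recode_vasari <- function(raw, map = default_recoding_map(),
                          schema = vasari_schema()) {
  need <- vapply(schema, `[[`, "", "name")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("VASARI table lacks declared columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  log <- list()
  out <- raw
  for (sc in schema) {
    nm <- sc$name
    if (sc$type == "numeric") {
      out[[nm]] <- as.numeric(raw[[nm]])
      next
    }
    x <- as.character(raw[[nm]])
    m <- map[[nm]]
    if (!is.null(m)) {
      # coded values are fixed points => idempotence
      m <- c(m, stats::setNames(unique(unname(m)), unique(unname(m))))
      x <- ifelse(is.na(x), NA_character_, unname(m[x]))
    }
    bad <- !is.na(as.character(raw[[nm]])) & is.na(x) |
      (!is.na(x) & !(x %in% sc$levels))
    if (any(bad)) {
      log[[nm]] <- sum(bad)
      x[bad] <- NA_character_
    }
    if (nrow(raw) > 0 && all(is.na(x)))
      warning("VASARI column '", nm, "' is entirely missing")
    out[[nm]] <- x
  }
  attr(out, "recode_log") <- log
  out
}

#' Encode coded VASARI records as a model design matrix
#'
#' Treatment (reference-level) dummy coding: binary items become a single
#' 0/1 indicator of the positive category; the ordinal edema item expands to
#' `medium` and `high` indicators against the `low` reference; nominal items
#' expand against their first declared level; numeric items pass through. A
#' level not present in the declared sets (e.g. appearing only at validation
#' time) is an error naming the level.
#'
#' @param records recoded data frame from [recode_vasari()].
#' @param schema a [vasari_schema()].
#' @return Numeric data frame (one column per dummy/numeric), rows aligned
#'   with `records`, with attribute `"reference_levels"`.
#' @export
encode_vasari <- function(records, schema = vasari_schema()) {
  out <- list()
  refs <- list()
  for (sc in schema) {
    nm <- sc$name
    x <- records[[nm]]
    if (sc$type == "numeric") {
      out[[nm]] <- as.numeric(x)
      next
    }
    x <- as.character(x)
    bad <- setdiff(stats::na.omit(unique(x)), sc$levels)
    if (length(bad))
      stop("unseen level(s) for '", nm, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (sc$type == "binary") {
      out[[nm]] <- as.numeric(x == sc$positive)
      refs[[nm]] <- setdiff(sc$levels, sc$positive)[1]
    } else {
      ref <- sc$levels[1]
      refs[[nm]] <- ref
      for (lv in sc$levels[-1])
        out[[paste0(nm, "_", lv)]] <- as.numeric(x == lv)
    }
  }
  res <- as.data.frame(out, check.names = FALSE)
  if ("patient_id" %in% names(records))
    rownames(res) <- records$patient_id
  attr(res, "reference_levels") <- refs
  res
}

#' Decode a design row back to the coded record (complete cases)
#'
#' Inverse of [encode_vasari()] for rows without missing values; used to
#' verify the encoding round-trip.
#'
#' @param design data frame from [encode_vasari()].
#' @param schema a [vasari_schema()].
#' @return Coded data frame.
#' @export
decode_vasari <- function(design, schema = vasari_schema()) {
  out <- list()
  for (sc in schema) {
    nm <- sc$name
    if (sc$type == "numeric") {
      out[[nm]] <- design[[nm]]
    } else if (sc$type == "binary") {
      ref <- setdiff(sc$levels, sc$positive)[1]
      out[[nm]] <- ifelse(design[[nm]] == 1, sc$positive, ref)
    } else {
      cols <- paste0(nm, "_", sc$levels[-1])
      m <- as.matrix(design[, cols, drop = FALSE])
      pick <- apply(m, 1, function(r)
        if (sum(r) == 0) sc$levels[1] else sc$levels[-1][which(r == 1)[1]])
      out[[nm]] <- pick
    }
  }
  as.data.frame(out, check.names = FALSE)
}
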