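#' Default harmonized semantic-feature schema
#'
#' The ordered feature list used throughout the package: general nodule
#' descriptors (margin, consistency, shape, margin conspicuity), internal
#' findings, and external findings. Margin is multi-label (a nodule may carry
#' several margin descriptors); the remaining general features are
#' single-choice categorical; internal and external findings are binary
#' present/absent. Any value may be MISSING, which is distinct from a binary
#' feature being absent.
#'
#' @return Object of class `semantic_schema`.
#' @export
default_schema <- function() {
  f <- list(
    list(name = "margin", display = "margin", type = "multilabel",
         group = "general",
         classes = c("smooth", "lobulated", "spiculated", "ill-defined")),
    list(name = "consistency", display = "consistency", type = "categorical",
         group = "general",
         classes = c("peri-cystic", "solid", "pure ground glass",
                     "semiconsolidation", "part-solid")),
    list(name = "shape", display = "shape", type = "categorical",
         group = "general",
         classes = c("irregular", "ovoid", "polygonal", "round")),
    list(name = "margin_conspicuity", display = "margin conspicuity",
         type = "categorical", group = "general",
         classes = c("well marginated", "poorly marginated")),
    list(name = "reticulation", display = "reticulation", type = "binary",
         group = "internal"),
    list(name = "cyst_like_spaces", display = "cyst-like spaces",
         type = "binary", group = "internal"),
    list(name = "necrosis", display = "necrosis", type = "binary",
         group = "internal"),
    list(name = "eccentric_calcification", display = "eccentric calcification",
         type = "binary", group = "internal"),
    list(name = "cavitation", display = "cavitation", type = "binary",
         group = "internal"),
    list(name = "bronchiectasis", display = "intra-nodular bronchiectasis",
         type = "binary", group = "internal"),
    list(name = "airway_cutoff", display = "airway cutoff", type = "binary",
         group = "internal"),
    list(name = "vascular_convergence", display = "vascular convergence",
         type = "binary", group = "external"),
    list(name = "pleural_retraction", display = "pleural retraction",
         type = "binary", group = "external"),
    list(name = "pleural_attachment", display = "pleural attachment",
         type = "binary", group = "external"),
    list(name = "emphysema", display = "paracicatricial emphysema",
         type = "binary", group = "external"),
    list(name = "septal_stretching", display = "septal stretching",
         type = "binary", group = "external")
  )
  names(f) <- vapply(f, `[[`, character(1), "name")
  for (i in seq_along(f)) {
    if (f[[i]]$type == "binary") f[[i]]$classes <- c("present", "absent")
    stopifnot(!anyDuplicated(f[[i]]$classes))
  }
  structure(list(features = f), class = "semantic_schema")
}

schema_feature_names <- function(schema) names(schema$features)

#' Construct a semantic record
#'
#' @param values Named list mapping feature name to value: a character vector
#'   of classes for categorical/multi-label features, a logical for binary
#'   features, or `NA` for MISSING. Features not listed are MISSING.
#' @param schema A [default_schema]-style schema.
#' @param patient_id,nodule_id Identifiers.
#' @return Object of class `semantic_record`.
#' @export
semantic_record <- function(values = list(), schema = default_schema(),
                            patient_id = NA_character_,
                            nodule_id = NA_character_) {
  rec <- stats::setNames(vector("list", length(schema$features)),
                         schema_feature_names(schema))
  for (nm in names(rec)) rec[[nm]] <- NA
  for (nm in names(values)) {
    if (!nm %in% names(rec)) stop("unknown feature: ", nm)
    v <- values[[nm]]
    ft <- schema$features[[nm]]
    if (length(v) == 1L && is.na(v)) {
      rec[[nm]] <- NA
    } else if (ft$type == "binary") {
      if (!is.logical(v) || length(v) != 1L) {
        stop("binary feature ", nm, " needs a single logical")
      }
      rec[[nm]] <- v
    } else {
      v <- as.character(v)
      if (!all(v %in% ft$classes)) {
        stop("value(s) outside schema vocabulary for ", nm, ": ",
             paste(setdiff(v, ft$classes), collapse = ", "))
      }
      if (ft$type == "categorical" && length(v) != 1L) {
        stop(nm, " is single-choice categorical")
      }
      rec[[nm]] <- unique(v)
    }
  }
  structure(list(patient_id = patient_id, nodule_id = nodule_id,
                 values = rec, schema = schema),
            class = "semantic_record")
}

record_is_missing <- function(rec, name) {
  v <- rec$values[[name]]
  length(v) == 1L && is.na(v)
}

#' Harmonize LIDC-style ordinal annotations into the package schema
#'
#' Maps 1-5 ordinal medians of the LIDC nodule characteristics (sphericity,
#' lobulation, texture, internal structure, margin, spiculation) onto the
#' harmonized schema using fixed thresholds: spiculation/lobulation >= 4 mark
#' the margin spiculated/lobulated; margin <= 2 marks it ill-defined, and an
#' otherwise unremarkable margin (>= 3, no lobulation/spiculation) is smooth;
#' texture 1-2 / 3 / 4-5 map to pure ground glass / part-solid / solid;
#' sphericity <= 2 / 3 / >= 4 map to irregular / ovoid / round; an internal
#' structure median of fluid or air marks cyst-like spaces present. Features
#' annotated only in the screening-cohort schema are left MISSING. The
#' thresholds are an explicit, overridable approximation (the source ordinal
#' scales carry no canonical cut points).
#'
#' @param raw Named list with any of `sphericity`, `lobulation`, `texture`,
#'   `internal_structure`, `margin`, `spiculation`; values in \[1, 5\]
#'   (medians may be fractional), missing fields omitted or `NA`.
#' @param schema Target schema.
#' @inheritParams semantic_record
#' @return A `semantic_record`.
#' @export
harmonize_lidc <- function(raw, schema = default_schema(),
                           patient_id = NA_character_,
                           nodule_id = NA_character_) {
  known <- c("sphericity", "lobulation", "texture", "internal_structure",
             "margin", "spiculation")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown LIDC fields: ", paste(extra, collapse = ", "))
  g <- function(nm) {
    v <- raw[[nm]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) return(NA_real_)
    v <- as.numeric(v)
    if (!is.finite(v) || v < 1 || v > 5) {
      stop("ordinal median out of range [1,5] for ", nm)
    }
    v
  }
  sph <- g("sphericity"); lob <- g("lobulation"); tex <- g("texture")
  istr <- g("internal_structure"); mar <- g("margin"); spic <- g("spiculation")

  values <- list()
  parts <- character(0)
  if (!is.na(spic) && spic >= 4) parts <- c(parts, "spiculated")
  if (!is.na(lob) && lob >= 4) parts <- c(parts, "lobulated")
  if (!is.na(mar) && mar <= 2) parts <- c(parts, "ill-defined")
  if (!is.na(mar) && mar > 2 && length(parts) == 0L) parts <- "smooth"
  if (length(parts)) values$margin <- parts
  if (!is.na(tex)) {
    values$consistency <- if (tex < 2.5) "pure ground glass"
      else if (tex < 3.5) "part-solid" else "solid"
  }
  if (!is.na(sph)) {
    values$shape <- if (sph >= 3.5) "round"
      else if (sph >= 2.5) "ovoid" else "irregular"
  }
  if (!is.na(istr)) {
    # internal structure codes: 1 soft tissue, 2 fluid, 3 fat, 4 air
    values$cyst_like_spaces <- round(istr) %in% c(2, 4)
  }
  semantic_record(values, schema = schema, patient_id = patient_id,
                  nodule_id = nodule_id)
}

#' Read semantic records from a CSV table
#'
#' One row per nodule; columns `patient_id`, `nodule_id`, then one column per
#' schema feature. Empty cells are MISSING; binary features use `present` /
#' `absent` (or TRUE/FALSE); multi-label values are separated by `;`.
#'
#' @param path CSV path.
#' @param schema Schema the values must belong to.
#' @return List of `semantic_record`.
#' @export
read_semantics_csv <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("patient_id", "nodule_id") %in% names(df)))
  feats <- intersect(schema_feature_names(schema), names(df))
  lapply(seq_len(nrow(df)), function(i) {
    values <- list()
    for (nm in feats) {
      cell <- df[i, nm]
      if (is.na(cell) || !nzchar(cell)) next
      ft <- schema$features[[nm]]
      values[[nm]] <- if (ft$type == "binary") {
        tolower(cell) %in% c("present", "true", "1")
      } else {
        trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
      }
    }
    semantic_record(values, schema = schema,
                    patient_id = df$patient_id[i], nodule_id = df$nodule_id[i])
  })
}

#' Write semantic records to CSV
#'
#' Inverse of [read_semantics_csv].
#'
#' @param records List of `semantic_record`.
#' @param path Output path.
#' @export
write_semantics_csv <- function(records, path) {
  schema <- records[[1]]$schema
  feats <- schema_feature_names(schema)
  rows <- lapply(records, function(r) {
    cells <- vapply(feats, function(nm) {
      v <- r$values[[nm]]
      if (length(v) == 1L && is.na(v)) return("")
      if (is.logical(v)) return(if (v) "present" else "absent")
      paste(v, collapse = ";")
    }, character(1))
    c(patient_id = r$patient_id, nodule_id = r$nodule_id, cells)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
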