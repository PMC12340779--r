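# Deterministic report templater.
#
# The structured-feature-to-text step is a deterministic template expansion
# producing a findings section (one sentence per observed feature, negatives
# included) and an impression section (a short salience-ordered summary of
# the observed general descriptors plus any present internal/external
# finding). A `text_provider` hook lets callers substitute a different
# generator (e.g. a large language model) without touching the rest of the
# pipeline.

finding_sentence <- function(ft, value) {
  if (ft$type == "binary") {
    if (isTRUE(value)) paste0("There is ", ft$display, ".")
    else paste0("No ", ft$display, ".")
  } else {
    paste0("The nodule ", ft$display, " is ",
           paste(value, collapse = " and "), ".")
  }
}

#' Render report-like text from a semantic record
#'
#' Pure function: equal records give byte-equal reports. The findings section
#' mentions every non-missing feature exactly once (binary absences as a
#' negative sentence); MISSING features are skipped entirely. The impression
#' summarizes the observed general descriptors and any present finding;
#' absences never appear in the impression. An all-missing record renders as
#' "No findings." in both sections so downstream text encoders always receive
#' input.
#'
#' @param rec A `semantic_record`.
#' @param text_provider Optional function `(rec) -> list(findings, impression)`
#'   overriding the built-in templater.
#' @return Object of class `report_text`: list of `findings` and `impression`
#'   sentence vectors.
#' @export
render_report <- function(rec, text_provider = NULL) {
  stopifnot(inherits(rec, "semantic_record"))
  if (!is.null(text_provider)) {
    out <- text_provider(rec)
    return(structure(list(findings = out$findings,
                          impression = out$impression),
                     class = "report_text"))
  }
  schema <- rec$schema
  observed <- names(which(!vapply(schema_feature_names(schema),
                                  function(n) record_is_missing(rec, n),
                                  logical(1))))
  if (length(observed) == 0L) {
    return(structure(list(findings = "No findings.",
                          impression = "No findings."),
                     class = "report_text"))
  }
  findings <- vapply(observed, function(nm) {
    finding_sentence(schema$features[[nm]], rec$values[[nm]])
  }, character(1))

  # impression: margin descriptors, then consistency, as noun-phrase
  # adjectives; shape as an apposition; present findings appended
  adjs <- character(0)
  if ("margin_conspicuity" %in% observed &&
      identical(rec$values$margin_conspicuity, "poorly marginated")) {
    adjs <- c(adjs, "poorly marginated")
  }
  if ("margin" %in% observed) adjs <- c(adjs, rec$values$margin)
  if ("consistency" %in% observed) adjs <- c(adjs, rec$values$consistency)
  head_np <- paste0("A ", paste(c(adjs, "nodule"), collapse = " "))
  if ("shape" %in% observed) {
    head_np <- paste0(head_np, ", ", rec$values$shape, " in shape")
  }
  present <- Filter(function(nm) {
    schema$features[[nm]]$type == "binary" && isTRUE(rec$values[[nm]])
  }, observed)
  impression <- paste0(head_np, ".")
  if (length(present)) {
    disp <- vapply(present, function(nm) schema$features[[nm]]$display,
                   character(1))
    joined <- if (length(disp) == 1L) disp else {
      paste(paste(disp[-length(disp)], collapse = ", "), "and",
            disp[length(disp)])
    }
    impression <- c(impression, paste0("There is associated ", joined, "."))
  }
  structure(list(findings = unname(findings), impression = impression),
            class = "report_text")
}

#' Default synonym lexicon for text augmentation
#'
#' A small packaged word list of non-clinical filler words and their
#' interchangeable synonyms. Class-vocabulary words never appear here, so
#' augmentation cannot corrupt a feature value.
#'
#' @export
default_lexicon <- function() {
  list(
    "is" = c("appears", "looks"),
    "appears" = c("is", "looks"),
    "associated" = c("accompanying", "adjacent"),
    "accompanying" = "associated",
    "shows" = c("demonstrates", "reveals"),
    "demonstrates" = c("shows", "reveals"),
    "seen" = c("noted", "observed", "identified"),
    "noted" = c("seen", "observed"),
    "observed" = c("seen", "noted"),
    "identified" = c("seen", "noted"),
    "reveals" = "shows",
    "findings" = "abnormality",
    "abnormality" = "findings"
  )
}

#' Text augmentation policy
#'
#' @param synonym_prob Per-word probability of replacing an eligible word with
#'   a lexicon synonym.
#' @param sentence_crop_prob Probability of keeping only a contiguous
#'   subsequence of the sentence list.
#' @param lexicon Word -> synonym-vector map; see [default_lexicon].
#' @export
text_aug_policy <- function(synonym_prob = 0.1, sentence_crop_prob = 0.3,
                            lexicon = default_lexicon()) {
  stopifnot(synonym_prob >= 0, synonym_prob <= 1,
            sentence_crop_prob >= 0, sentence_crop_prob <= 1)
  structure(list(synonym_prob = synonym_prob,
                 sentence_crop_prob = sentence_crop_prob,
                 lexicon = lexicon),
            class = "text_aug_policy")
}

#' Augment report text
#'
#' Independently replaces eligible (lexicon) words with synonyms and, with
#' `sentence_crop_prob`, keeps a random contiguous subsequence of sentences.
#' The output is never empty, and words outside the lexicon (in particular
#' all class vocabulary) are never substituted. A zero-probability policy is
#' the identity.
#'
#' @param sentences Character vector of sentences.
#' @param policy A [text_aug_policy].
#' @param seed Optional seed for reproducibility.
#' @export
augment_text <- function(sentences, policy = text_aug_policy(), seed = NULL) {
  stopifnot(length(sentences) >= 1L)
  if (policy$synonym_prob == 0 && policy$sentence_crop_prob == 0) {
    return(sentences)
  }
  with_seed(seed, {
    out <- vapply(sentences, function(s) {
      words <- strsplit(s, " ", fixed = TRUE)[[1]]
      for (i in seq_along(words)) {
        key <- tolower(gsub("[[:punct:]]+$", "", words[i]))
        syns <- policy$lexicon[[key]]
        if (!is.null(syns) && stats::runif(1) < policy$synonym_prob) {
          repl <- if (length(syns) == 1L) syns else sample(syns, 1)
          tail_punct <- sub("^[^[:punct:]]*", "", words[i])
          words[i] <- paste0(repl, tail_punct)
        }
      }
      paste(words, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    if (stats::runif(1) < policy$sentence_crop_prob && length(out) > 1L) {
      i <- sample.int(length(out), 1)
      j <- i + sample.int(length(out) - i + 1L, 1) - 1L
      out <- out[i:j]
    }
    out
  })
}

#' Select the training text for one sample
#'
#' Returns the findings or the impression section with probability one half
#' each, matching the training-time sampling of report sections.
#'
#' @param report A `report_text`.
#' @param seed Optional seed.
#' @export
select_training_text <- function(report, seed = NULL) {
  stopifnot(inherits(report, "report_text"))
  with_seed(seed, {
    if (stats::runif(1) < 0.5) report$findings else report$impression
  })
}
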