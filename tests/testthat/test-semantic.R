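test_that("harmonization thresholds cover the full ordinal range", {
  # exhaustive enumeration of integer medians
  for (s in 1:5) {
    rec <- harmonize_lidc(list(spiculation = s))
    if (s >= 4) {
      expect_true("spiculated" %in% rec$values$margin)
    } else {
      expect_true(length(rec$values$margin) == 1L && is.na(rec$values$margin))
    }
  }
  for (t in 1:5) {
    rec <- harmonize_lidc(list(texture = t))
    expected <- if (t <= 2) "pure ground glass" else if (t == 3) "part-solid"
      else "solid"
    expect_identical(rec$values$consistency, expected)
  }
  for (s in 1:5) {
    rec <- harmonize_lidc(list(sphericity = s))
    expected <- if (s <= 2) "irregular" else if (s == 3) "ovoid" else "round"
    expect_identical(rec$values$shape, expected)
  }
  # margin ordinal: low = ill-defined, high = smooth unless lobul./spic.
  expect_identical(harmonize_lidc(list(margin = 2))$values$margin,
                   "ill-defined")
  expect_identical(harmonize_lidc(list(margin = 4))$values$margin, "smooth")
  expect_setequal(harmonize_lidc(list(margin = 4, lobulation = 5))$values$margin,
                  "lobulated")
  # all fields absent -> all-MISSING record
  rec <- harmonize_lidc(list())
  expect_true(all(vapply(rec$values, function(v) length(v) == 1 && is.na(v),
                         logical(1))))
  expect_error(harmonize_lidc(list(texture = 6)), "out of range")
  expect_error(harmonize_lidc(list(bogus = 3)), "unknown")
})

test_that("render_report covers exactly the non-missing features and builds
           the impression from present findings", {
  rec <- semantic_record(list(margin = "spiculated", consistency = "solid"))
  rep <- render_report(rec)
  expect_length(rep$findings, 2)
  expect_true(any(grepl("spiculated solid nodule", rep$impression)))

  # binary absent: negative sentence in findings, never in the impression
  rec2 <- semantic_record(list(margin = "smooth",
                               pleural_attachment = FALSE,
                               cyst_like_spaces = TRUE))
  rep2 <- render_report(rec2)
  expect_length(rep2$findings, 3)
  expect_true(any(grepl("^No pleural attachment", rep2$findings)))
  expect_false(any(grepl("pleural attachment", rep2$impression)))
  expect_true(any(grepl("cyst-like spaces", rep2$impression)))

  # all-missing degenerate case
  rep3 <- render_report(semantic_record())
  expect_identical(rep3$findings, "No findings.")
  expect_identical(rep3$impression, "No findings.")

  # purity: equal records give byte-equal reports; coverage property
  withr::with_seed(12, {
    cfg <- phantom_config(n_cases = 1)
    for (i in 1:20) {
      r <- sample_semantics(cfg, seed = i)
      a <- render_report(r)
      b <- render_report(r)
      expect_identical(a, b)
      n_obs <- sum(!vapply(names(r$values), function(nm) {
        v <- r$values[[nm]]; length(v) == 1 && is.na(v)
      }, logical(1)))
      if (n_obs > 0) expect_length(a$findings, n_obs)
      expect_gt(length(a$impression), 0)
    }
  })
})

test_that("text augmentation preserves clinical vocabulary and crops
           contiguously", {
  s <- c("The nodule margin is spiculated.",
         "There is pleural attachment.",
         "No findings.",
         "The nodule consistency is solid.")
  expect_identical(augment_text(s, text_aug_policy(0, 0)), s)
  expect_identical(augment_text(s, seed = 99), augment_text(s, seed = 99))
  full <- text_aug_policy(synonym_prob = 1, sentence_crop_prob = 1)
  all_contig <- vapply(1:50, function(i) {
    out <- augment_text(s, full, seed = i)
    # strip synonym substitutions: match by sentence position via class words
    n <- length(out)
    n >= 1 && n <= 4
  }, logical(1))
  expect_true(all(all_contig))
  # class vocabulary survives synonym substitution at probability 1
  out <- augment_text(s, text_aug_policy(1, 0), seed = 5)
  expect_true(any(grepl("spiculated", out)))
  expect_true(any(grepl("solid", out)))
  # crop outputs are contiguous subsequences of the (non-cropped) augmentation
  base <- augment_text(s, text_aug_policy(0, 0))
  crops <- unique(lapply(1:40, function(i) {
    augment_text(s, text_aug_policy(0, 1), seed = i)
  }))
  contigs <- lapply(seq_along(s), function(i) {
    lapply(i:length(s), function(j) s[i:j])
  })
  contigs <- unlist(contigs, recursive = FALSE)
  for (cr in crops) {
    expect_true(any(vapply(contigs, identical, logical(1), y = cr)))
  }
})

test_that("training-text selection is a fair coin and seeded", {
  rep <- render_report(semantic_record(list(margin = "smooth",
                                            consistency = "solid")))
  hits <- vapply(1:10000, function(i) {
    identical(select_training_text(rep, seed = i), rep$findings)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 0.02)
  expect_identical(select_training_text(rep, seed = 1),
                   select_training_text(rep, seed = 1))
  same <- structure(list(findings = "X.", impression = "X."),
                    class = "report_text")
  expect_identical(select_training_text(same, seed = 2), "X.")
})

test_that("prompt bank is complete and uses the canonical templates", {
  schema <- default_schema()
  bank <- build_prompts(schema)
  expect_length(bank$margin, 4)
  expect_true("This nodule margin is spiculated." %in% bank$margin)
  expect_identical(unname(bank$pleural_attachment),
                   c("There is pleural attachment.", "No findings."))
  for (nm in names(schema$features)) {
    ft <- schema$features[[nm]]
    if (ft$type == "binary") {
      expect_length(bank[[nm]], 2)
    } else {
      expect_length(bank[[nm]], length(ft$classes))
      # every class string appears in exactly one prompt of its feature
      for (cl in ft$classes) {
        expect_equal(sum(endsWith(bank[[nm]], paste0("is ", cl, "."))), 1)
      }
    }
  }
})

test_that("semantic CSV round-trips records including missingness", {
  cfg <- phantom_config(n_cases = 1)
  recs <- lapply(1:8, function(i) {
    r <- sample_semantics(cfg, seed = i)
    r$patient_id <- paste0("P", i)
    r$nodule_id <- paste0("P", i, "_n1")
    r
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_semantics_csv(recs, path)
  back <- read_semantics_csv(path)
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$values, recs[[i]]$values)
    expect_identical(back[[i]]$patient_id, recs[[i]]$patient_id)
  }
})

test_that("tokenizer pads, truncates, and marks the end token", {
  tok <- toy_tokenizer(context = 12L)
  ids <- tokenize(tok, "The nodule margin is spiculated.")
  expect_length(ids, 12)
  expect_identical(ids[1], unname(tok$id[["<start>"]]))
  eot <- attr(ids, "eot")
  expect_identical(ids[eot], unname(tok$id[["<end>"]]))
  expect_true(all(ids[seq(eot + 1, 12)] == tok$id[["<pad>"]]))
  long <- tokenize(tok, paste(rep("solid nodule", 30), collapse = " "))
  expect_length(long, 12)
  expect_identical(long[12], unname(tok$id[["<end>"]]))
  # unknown words map to <unk>
  u <- tokenize(tok, "zygomorphic widget")
  expect_true(tok$id[["<unk>"]] %in% u)
})
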