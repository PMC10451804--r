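test_that("sectionizing splits on conventional headers", {
  note <- sectionize("FINDINGS: clear lungs. IMPRESSION: no acute disease.")
  expect_setequal(names(note$sections), c("findings", "impression"))
  expect_match(note$sections$findings, "clear lungs")
  # headerless notes land in 'other'
  plain <- sectionize("Lungs are clear bilaterally.")
  expect_identical(names(plain$sections), "other")
  # repeated headers append to the same section
  dup <- sectionize("FINDINGS: one. IMPRESSION: a. FINDINGS: two.")
  expect_match(dup$sections$findings, "one")
  expect_match(dup$sections$findings, "two")
  # preamble before the first header
  pre <- sectionize("Portable film. FINDINGS: clear.")
  expect_match(pre$sections$other, "Portable")
  expect_error(sectionize("   "), "non-empty")
})

test_that("mention finding locates keywords with morphology", {
  m <- find_mentions("Bilateral airspace opacities.")
  expect_identical(nrow(m), 1L)
  expect_identical(m$keyword, "opacity")
  m2 <- find_mentions("No opacity. Opacities persist.")
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$sentence_index, c(1L, 2L))
  expect_identical(nrow(find_mentions("Heart size is normal.")), 0L)
  # opacification is an opacity-family word
  expect_identical(find_mentions("Diffuse opacification.")$keyword, "opacity")
})

test_that("polarity honours negation, uncertainty and scope resets", {
  s1 <- "No focal opacity or effusion."
  expect_identical(classify_polarity(s1, regexpr("opacity", s1)), "negative")
  expect_identical(classify_polarity(s1, regexpr("effusion", s1)), "negative")
  s2 <- "Possible right basilar consolidation."
  expect_identical(classify_polarity(s2, regexpr("consolidation", s2)),
                   "uncertain")
  # the conjunction resets negation scope
  s3 <- "Effusions resolved but new opacity at the left base."
  expect_identical(classify_polarity(s3, regexpr("Effusions", s3)),
                   "negative")
  expect_identical(classify_polarity(s3, regexpr("opacity", s3)), "positive")
  # negation outranks uncertainty in the same clause
  s4 <- "No possible pneumothorax."
  expect_identical(classify_polarity(s4, regexpr("pneumothorax", s4)),
                   "negative")
})

test_that("laterality picks the nearest descriptor", {
  s1 <- "Bilateral pleural effusions."
  expect_identical(assign_laterality(s1, regexpr("effusions", s1)),
                   "bilateral")
  s2 <- "Right lower lobe pneumonia."
  expect_identical(assign_laterality(s2, regexpr("pneumonia", s2)), "right")
  s3 <- "Patchy opacities bilaterally."
  expect_identical(assign_laterality(s3, regexpr("opacities", s3)),
                   "bilateral")
  s4 <- "Bibasilar atelectasis."
  expect_identical(assign_laterality(s4, regexpr("atelectasis", s4)),
                   "bilateral")
  s5 <- "There is consolidation."
  expect_identical(assign_laterality(s5, regexpr("consolidation", s5)),
                   "none")
})

test_that("note labels combine mention evidence per the laterality rules", {
  expect_identical(
    label_note("Bilateral airspace opacities consistent with edema.")$bilateral_opacities,
    "positive")
  # strictly unilateral findings are negative for bilateral opacities
  expect_identical(
    label_note("Right lower lobe opacity. Left lung clear.")$bilateral_opacities,
    "negative")
  expect_identical(
    label_note("No focal consolidation, effusion, or pneumothorax.")$bilateral_opacities,
    "negative")
  # separate left- and right-sided positives combine to bilateral
  expect_identical(
    label_note("Right basilar opacity. New left basilar opacity.")$bilateral_opacities,
    "positive")
  combine_off <- labeler_rules(combine_left_right = FALSE)
  expect_identical(
    label_note("Right basilar opacity. New left basilar opacity.",
               rules = combine_off)$bilateral_opacities,
    "negative")
  # impression outranks findings on conflict
  conflict <- paste("FINDINGS: Bilateral opacities.",
                    "IMPRESSION: No opacities; lungs clear.")
  expect_identical(label_note(conflict)$bilateral_opacities, "negative")
  expect_error(label_note(""), "empty")
})

test_that("negation prefix flips every screening keyword", {
  sentences <- c(ards = "Findings compatible with ARDS.",
                 atelectasis = "Atelectasis at the left base.",
                 consolidation = "Consolidation in both lungs.",
                 edema = "Edema is seen bilaterally.",
                 effusion = "Effusion on the right.",
                 opacity = "Opacity in both lung bases.",
                 infiltrates = "Infiltrates seen bilaterally.",
                 pneumonia = "Pneumonia in the right lobe.",
                 pneumothorax = "Pneumothorax on the left.")
  for (kw in names(sentences)) {
    pos <- find_mentions(sentences[[kw]], lexicon = kw)
    expect_identical(classify_polarity(pos$sentence[1], pos$start[1]),
                     "positive", info = kw)
    s <- sentences[[kw]]
    negated <- paste("No", paste0(tolower(substr(s, 1, 1)),
                                  substr(s, 2, nchar(s))))
    neg <- find_mentions(negated, lexicon = kw)
    expect_identical(classify_polarity(neg$sentence[1], neg$start[1]),
                     "negative", info = kw)
  }
})

test_that("labeling is invariant to whitespace normalization", {
  base <- "FINDINGS: Bilateral opacities.  IMPRESSION: Bilateral edema."
  squashed <- gsub("\\s+", " ", base)
  expect_identical(label_note(base)$bilateral_opacities,
                   label_note(squashed)$bilateral_opacities)
})

test_that("generated notes are deterministic and label as intended", {
  n1 <- generate_note("positive", seed = 5)
  n2 <- generate_note("positive", seed = 5)
  expect_identical(n1, n2)
  for (target in c("positive", "negative", "uncertain")) {
    for (seed in 1:12) {
      note <- generate_note(target, seed = seed)
      expect_identical(label_note(note$text)$bilateral_opacities,
                       note$intended,
                       info = paste(target, seed))
    }
  }
})

test_that("note labels benchmark against adjudicated truth", {
  # faithful notes: perfect precision and sensitivity
  adjud <- c("present", "present", "absent", "absent", "equivocal")
  notes <- c("positive", "positive", "negative", "negative", "uncertain")
  bm <- benchmark_against_truth(notes, adjud)
  expect_equal(bm$metrics$precision, 1)
  expect_equal(bm$metrics$sensitivity, 1)
  # uncertain handled as positive when configured
  bm2 <- benchmark_against_truth(notes, adjud, uncertain = "positive")
  expect_identical(bm2$counts$FP, 1L)
  expect_warning(benchmark_against_truth(c("uncertain"), c("present")),
                 "no pairs")
})
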