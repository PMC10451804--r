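# Rule-based labeling of radiology notes for bilateral pulmonary
# opacities: sectionizing, keyword mention finding, negation/uncertainty
# polarity, laterality assignment, and note-level label combination.

OPACITY_KEYWORDS <- c("ards", "atelectasis", "consolidation", "edema",
                      "effusion", "opacity", "infiltrates", "pneumonia",
                      "pneumothorax")

# Keywords that count as parenchymal airspace-opacity evidence for the
# note-level bilateral-opacities label (the remaining screening keywords
# can be enabled via labeler_rules()).
PARENCHYMAL_KEYWORDS <- c("opacity", "infiltrates", "consolidation",
                          "edema", "pneumonia", "ards")

# Regex variants per keyword (case-insensitive, simple morphology).
.keyword_patterns <- c(
  ards = "\\bards\\b",
  atelectasis = "\\batelecta\\w*",
  consolidation = "\\bconsolidat\\w*",
  edema = "\\bedema\\b",
  effusion = "\\beffusions?\\b",
  opacity = "\\bopacit\\w*|\\bopacifi\\w*",
  infiltrates = "\\binfiltrat\\w*",
  pneumonia = "\\bpneumonia\\b",
  pneumothorax = "\\bpneumothora\\w*")

#' Labeler rules
#'
#' @param negation_cues phrases that negate a finding within a clause.
#' @param uncertainty_cues phrases that mark a finding as uncertain.
#' @param scope_resets conjunctions that end a cue's scope.
#' @param opacity_keywords keywords that count as airspace-opacity
#'   evidence for the note-level label.
#' @param combine_left_right if \code{TRUE} (default), separate positive
#'   right-sided and left-sided opacity mentions combine to a
#'   bilateral-positive note label.
#' @return a list of rule settings.
#' @export
labeler_rules <- function(negation_cues = c("no", "without", "free of",
                                            "resolved", "clear of",
                                            "negative for", "absence of"),
                          uncertainty_cues = c("possible", "possibly",
                                               "may represent",
                                               "cannot exclude",
                                               "cannot be excluded",
                                               "cannot rule out",
                                               "questionable", "probable",
                                               "suspected", "vs",
                                               "concerning for"),
                          scope_resets = c("but", "however", "although"),
                          opacity_keywords = PARENCHYMAL_KEYWORDS,
                          combine_left_right = TRUE) {
  list(negation_cues = negation_cues, uncertainty_cues = uncertainty_cues,
       scope_resets = scope_resets, opacity_keywords = opacity_keywords,
       combine_left_right = combine_left_right)
}

# Abbreviations whose trailing period must not split a sentence.
.abbrev_guard <- c("dr", "mr", "mrs", "ms", "st", "a\\.m", "p\\.m", "no",
                   "e\\.g", "i\\.e", "approx", "cm", "mm")

# Split text into sentences on periods/newlines, guarding common
# abbreviations and decimal numbers.
.split_sentences <- function(text) {
  guarded <- gsub("(\\d)\\.(\\d)", "\\1<DOT>\\2", text)
  for (ab in .abbrev_guard)
    guarded <- gsub(paste0("\\b(", ab, ")\\."), "\\1<DOT>",
                    guarded, ignore.case = TRUE)
  parts <- unlist(strsplit(guarded, "(?<=[.!?])\\s+|\\n+", perl = TRUE))
  parts <- gsub("<DOT>", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Split a radiology note into sections
#'
#' Splits on conventional colon-terminated headers (INDICATION,
#' COMPARISON, TECHNIQUE, FINDINGS, IMPRESSION; case-insensitive). Text
#' before any header goes to section \code{"other"}; repeated headers
#' append to the same section.
#'
#' @param text raw note text (non-empty).
#' @return an object of class \code{radiology_note}: list with
#'   \code{text} and named \code{sections}.
#' @export
sectionize <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("note text must be a non-empty string")
  header_re <- "(?i)\\b(indication|comparison|technique|history|findings|impression)\\s*:"
  m <- gregexpr(header_re, text, perl = TRUE)[[1]]
  sections <- list()
  add <- function(name, chunk) {
    chunk <- trimws(chunk)
    if (!nzchar(chunk)) return()
    name <- tolower(name)
    if (!name %in% c("indication", "comparison", "findings", "impression"))
      name <- "other"
    sections[[name]] <<- paste(c(sections[[name]], chunk), collapse = " ")
  }
  if (m[1] == -1L) {
    add("other", text)
  } else {
    if (m[1] > 1L) add("other", substr(text, 1L, m[1] - 1L))
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      header <- substr(text, m[i], m[i] + lens[i] - 1L)
      name <- tolower(gsub("[^a-zA-Z]", "", header))
      from <- m[i] + lens[i]
      to <- if (i < length(m)) m[i + 1L] - 1L else nchar(text)
      add(name, substr(text, from, to))
    }
  }
  structure(list(text = text, sections = sections),
            class = "radiology_note")
}

#' Find finding-keyword mentions
#'
#' One mention per keyword occurrence, with its section, sentence index,
#' character span within the sentence, and (initially unset) polarity
#' and laterality.
#'
#' @param note a \code{radiology_note} (from \code{\link{sectionize}}) or
#'   raw text.
#' @param lexicon keyword set to search for (default: the nine screening
#'   keywords).
#' @return data.frame of mentions.
#' @export
find_mentions <- function(note, lexicon = OPACITY_KEYWORDS) {
  if (is.character(note)) note <- sectionize(note)
  if (length(lexicon) == 0L) stop("lexicon must be non-empty")
  rows <- list(); k <- 0L
  for (sec in names(note$sections)) {
    sentences <- .split_sentences(note$sections[[sec]])
    for (si in seq_along(sentences)) {
      sent <- sentences[si]
      for (kw in lexicon) {
        pat <- .keyword_patterns[[kw]]
        if (is.null(pat) || is.na(pat)) pat <- paste0("\\b", kw, "\\w*")
        mm <- gregexpr(pat, sent, ignore.case = TRUE, perl = TRUE)[[1]]
        if (mm[1] == -1L) next
        lens <- attr(mm, "match.length")
        for (j in seq_along(mm)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            keyword = kw, section = sec, sentence_index = si,
            sentence = sent, start = as.integer(mm[j]),
            end = as.integer(mm[j] + lens[j] - 1L),
            polarity = NA_character_, laterality = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(keyword = character(0), section = character(0),
                      sentence_index = integer(0), sentence = character(0),
                      start = integer(0), end = integer(0),
                      polarity = character(0), laterality = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Split a sentence into clauses at scope-resetting conjunctions, and
# return the clause (character range) containing position `pos`.
.clause_of <- function(sentence, pos, scope_resets) {
  pat <- paste0("(?i)\\b(", paste(scope_resets, collapse = "|"), ")\\b")
  m <- gregexpr(pat, sentence, perl = TRUE)[[1]]
  bounds <- c(0L, if (m[1] != -1L) as.integer(m), nchar(sentence) + 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    if (pos > bounds[i] && pos < bounds[i + 1L])
      return(substr(sentence, bounds[i] + 1L, bounds[i + 1L] - 1L))
  }
  sentence
}

#' Classify mention polarity
#'
#' A mention is negative if a negation cue shares its clause (clauses
#' are sentence segments delimited by scope-resetting conjunctions such
#' as "but"/"however"); uncertain if an uncertainty cue shares the
#' clause; positive otherwise. Negation outranks uncertainty when both
#' apply.
#'
#' @param sentence the sentence text.
#' @param start character position of the mention in the sentence.
#' @param rules a \code{\link{labeler_rules}} list.
#' @return \code{"positive"}, \code{"negative"}, or \code{"uncertain"}.
#' @export
classify_polarity <- function(sentence, start, rules = labeler_rules()) {
  clause <- .clause_of(sentence, start, rules$scope_resets)
  has_cue <- function(cues) {
    pat <- paste0("(?i)\\b(", paste(cues, collapse = "|"), ")\\b")
    grepl(pat, clause, perl = TRUE)
  }
  if (has_cue(rules$negation_cues)) "negative"
  else if (has_cue(rules$uncertainty_cues)) "uncertain"
  else "positive"
}

.laterality_patterns <- list(
  bilateral = "(?i)\\b(bilateral(ly)?|bibasilar|both\\s+lungs?|both\\s+(lung\\s+)?bases|diffuse(ly)?\\s+(bilateral)?)\\b",
  right = "(?i)\\bright\\b",
  left = "(?i)\\bleft\\b")

#' Assign mention laterality
#'
#' The nearest laterality descriptor in the same sentence wins:
#' "bilateral(ly)", "bibasilar", "both lungs/bases" map to bilateral;
#' "right"/"left" (including lobe phrases) map accordingly; no
#' descriptor yields \code{"none"}.
#'
#' @param sentence the sentence text.
#' @param start character position of the mention.
#' @return \code{"bilateral"}, \code{"right"}, \code{"left"} or
#'   \code{"none"}.
#' @export
assign_laterality <- function(sentence, start) {
  best <- "none"; best_dist <- Inf
  for (lat in names(.laterality_patterns)) {
    m <- gregexpr(.laterality_patterns[[lat]], sentence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (p in as.integer(m)) {
      d <- abs(p - start)
      if (d < best_dist) { best_dist <- d; best <- lat }
    }
  }
  best
}

# Annotate a mention table with polarity and laterality.
.annotate_mentions <- function(mentions, rules) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions$polarity <- vapply(seq_len(nrow(mentions)), function(i)
    classify_polarity(mentions$sentence[i], mentions$start[i], rules),
    character(1))
  mentions$laterality <- vapply(seq_len(nrow(mentions)), function(i)
    assign_laterality(mentions$sentence[i], mentions$start[i]),
    character(1))
  mentions
}

# Note-level decision from an annotated opacity-type mention subset.
.decide_from_mentions <- function(m, rules) {
  if (nrow(m) == 0L) return("negative")
  pos <- m[m$polarity == "positive", , drop = FALSE]
  unc <- m[m$polarity == "uncertain", , drop = FALSE]
  if (any(pos$laterality == "bilateral")) return("positive")
  if (rules$combine_left_right &&
      any(pos$laterality == "left") && any(pos$laterality == "right"))
    return("positive")
  if (any(unc$laterality %in% c("bilateral", "none")) ||
      (rules$combine_left_right &&
       any(unc$laterality == "left") && any(unc$laterality == "right")))
    return("uncertain")
  # positive mentions without laterality are nonspecific evidence:
  # opacities are described but their distribution is not
  if (any(pos$laterality == "none")) return("uncertain")
  "negative"
}

#' Label a radiology note for bilateral opacities
#'
#' Combines annotated opacity-type mentions into a note-level label:
#' positive if a positive mention carries bilateral laterality (or
#' positive mentions exist on both sides, when enabled); negative when
#' all opacity-type mentions are negated or strictly unilateral;
#' uncertain when the best evidence is an uncertain or
#' non-lateralized mention. Impression-section mentions outrank
#' findings-section mentions on conflict.
#'
#' @param note raw text or a \code{radiology_note}.
#' @param lexicon screening keywords to detect.
#' @param rules a \code{\link{labeler_rules}} list.
#' @return an object of class \code{note_label}: list with
#'   \code{bilateral_opacities} in \{positive, negative, uncertain\} and
#'   the supporting \code{mentions} table.
#' @export
label_note <- function(note, lexicon = OPACITY_KEYWORDS,
                       rules = labeler_rules()) {
  if (is.character(note)) {
    if (length(note) != 1L || !nzchar(trimws(note))) stop("empty note")
    note <- sectionize(note)
  }
  mentions <- .annotate_mentions(find_mentions(note, lexicon), rules)
  # the clinical indication/comparison state the question, not findings
  op <- mentions[mentions$keyword %in% rules$opacity_keywords &
                   !mentions$section %in% c("indication", "comparison"), ,
                 drop = FALSE]
  imp <- op[op$section == "impression", , drop = FALSE]
  label <- if (nrow(imp) > 0L) .decide_from_mentions(imp, rules)
           else .decide_from_mentions(op, rules)
  structure(list(bilateral_opacities = label, mentions = mentions),
            class = "note_label")
}

# --- synthetic note generation ---------------------------------------------

.note_templates <- list(
  positive = c(
    "Bilateral airspace opacities consistent with edema.",
    "Patchy opacities are seen bilaterally.",
    "Bibasilar consolidation is present.",
    "Diffuse bilateral infiltrates compatible with pneumonia.",
    "Right lower lobe opacity. Left basilar opacity is also seen.",
    "Bilateral pleural-based opacities with associated consolidation."),
  negative = c(
    "No focal consolidation, effusion, or pneumothorax.",
    "Lungs are clear of opacity.",
    "Right lower lobe opacity. Left lung remains clear.",
    "Previously seen infiltrates resolved.",
    "No opacity or edema identified.",
    "Left basilar opacity only; the right lung is clear."),
  uncertain = c(
    "Possible bilateral opacities; clinical correlation recommended.",
    "Bilateral infiltrates cannot be excluded.",
    "Questionable bibasilar consolidation.",
    "Hazy opacification, possibly bilateral edema.",
    "Findings may represent bilateral pneumonia."))

.note_distractors <- c(
  "Endotracheal tube in standard position.",
  "Cardiomediastinal silhouette is stable.",
  "Degenerative changes of the thoracic spine.",
  "Central venous catheter tip at the cavoatrial junction.",
  "No displaced rib fracture.")

#' Generate a synthetic radiology note
#'
#' Fills a sectioned note template (INDICATION / FINDINGS / IMPRESSION,
#' with device and bone distractor sentences) whose rule-based label
#' provably equals the requested target. Deterministic given the seed.
#'
#' @param target \code{"positive"}, \code{"negative"} or
#'   \code{"uncertain"}.
#' @param seed integer seed.
#' @return list with \code{text} and \code{intended} label.
#' @export
generate_note <- function(target = c("positive", "negative", "uncertain"),
                          seed = 1L) {
  target <- match.arg(target)
  set.seed(as.integer(seed))
  key_sent <- sample(.note_templates[[target]], 1L)
  distract <- sample(.note_distractors, 2L)
  text <- paste0(
    "INDICATION: Sepsis, evaluate for ARDS.\n",
    "FINDINGS: ", distract[1], " ", key_sent, " ", distract[2], "\n",
    "IMPRESSION: ", key_sent)
  list(text = text, intended = target)
}

#' Benchmark note labels against adjudicated image labels
#'
#' Maps note labels to a binary present/absent call and compares them to
#' adjudicated ground truth using the evaluation module.
#'
#' @param note_labels character vector in \{positive, negative,
#'   uncertain\}.
#' @param adjudicated character vector in \{present, absent, equivocal\}.
#' @param uncertain one of \code{"exclude"} (default) or
#'   \code{"positive"}: how uncertain note labels are handled.
#' @return list with \code{counts} (\code{confusion_counts}) and
#'   \code{metrics} (\code{diagnostic_metrics}).
#' @export
benchmark_against_truth <- function(note_labels, adjudicated,
                                    uncertain = c("exclude", "positive")) {
  uncertain <- match.arg(uncertain)
  if (length(note_labels) != length(adjudicated) || length(note_labels) == 0L)
    stop("paired non-empty note and image labels required")
  keep <- rep(TRUE, length(note_labels))
  pred <- as.integer(note_labels == "positive")
  if (uncertain == "exclude") keep <- note_labels != "uncertain"
  else pred[note_labels == "uncertain"] <- 1L
  truth <- as.integer(adjudicated == "present")
  if (!any(keep)) {
    warning("no pairs remain after excluding uncertain notes")
    return(list(counts = NULL, metrics = NULL))
  }
  counts <- confusion_counts(truth[keep], pred[keep])
  list(counts = counts, metrics = diagnostic_metrics(counts))
}
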