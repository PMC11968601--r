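# ---------------------------------------------------------------------------
# Synthetic paired-report generator. Emulates, at desk scale, a corpus of
# breast MRI reports: per record a latent descriptor per category, a logistic
# label process in which biopsy-leaning descriptors (washout kinetics,
# irregular/spiculated margins, suspicious nodes) raise P(biopsy), per-category
# missingness (optionally label-informative), and an optional personal-history
# clause whose family ("prior carcinoma" vs "routine screening") can itself
# enter the label model.
# ---------------------------------------------------------------------------

# label-model features: each maps to a (category, lexicon term) pair, except
# ph_malignant which flags the malignant-leaning personal-history family.
label_features <- function() {
  list(
    washout          = c(category = "dce_curve_assessment",  term = "washout enhancement curve"),
    irregular_mass   = c(category = "mass_non_mass",         term = "irregular mass"),
    spiculated_mass  = c(category = "mass_non_mass",         term = "spiculated mass"),
    suspicious_nodes = c(category = "axillary_lymph_nodes",  term = "suspicious axillary nodes"),
    skin_thickening  = c(category = "skin_lesions",          term = "skin thickening"),
    ph_malignant     = c(category = NA_character_, term = NA_character_)
  )
}

#' Default log-odds weights of the synthetic label model
#'
#' Biopsy-leaning descriptors (washout kinetics, irregular or spiculated
#' margins, suspicious axillary nodes, skin thickening) and the
#' malignant-leaning personal-history family raise the probability of the
#' "Suggestion for Biopsy" label. Together with the default intercept (-0.9)
#' these weights put the biopsy prevalence near 0.7, in the neighbourhood of
#' a screening-referral MRI cohort.
#'
#' @return Named numeric vector of feature weights.
#' @export
default_beta <- function() {
  c(washout = 1.6, irregular_mass = 1.2, spiculated_mass = 1.8,
    suspicious_nodes = 1.2, skin_thickening = 0.6, ph_malignant = 1.0)
}

# sentence surface variants; {term} is replaced by the latent descriptor.
# Wording deliberately avoids every lexicon term so term routing is exact.
sentence_templates <- function() {
  c("The study shows {term}",
    "There is {term} on the current examination",
    "Imaging demonstrates {term}",
    "Noted on review: {term}")
}

ph_clauses <- function() {
  list(
    malignant = c(
      "Personal history: post-surgery for prior carcinoma, on follow-up",
      "Status post lumpectomy, under close follow-up"
    ),
    benign = c(
      "Personal history: routine screening follow-up",
      "No prior interventions, annual follow-up visit"
    )
  )
}

#' Configuration for the synthetic report generator
#'
#' @param n Number of records (>= 1).
#' @param seed RNG seed driving every stochastic choice of the generator.
#' @param miss_rate Per-category probability that the category is omitted
#'   from the free text; either a single value recycled over the ten
#'   categories or a named vector. Default 0.3.
#' @param ph_rate Probability a personal-history clause is appended.
#' @param beta Named log-odds weights of the label model; names must be
#'   features known to [label_features()].
#' @param beta0 Intercept of the label model.
#' @param missingness_mode `"informative"` (default): the omission
#'   probability of a category whose latent descriptor is a biopsy-leaning
#'   term is multiplied by `informative_factor`, so the missingness pattern
#'   itself carries label signal. `"MCAR"`: omission is independent of
#'   everything.
#' @param informative_factor Multiplier in `[0,1]` applied under informative
#'   missingness (default 0.25: malignant-leaning findings are rarely left
#'   out of the narrative).
#' @param withhold_from_text Categories always omitted from the free text but
#'   retained in the structured half — used to construct corpora where the
#'   two streams carry complementary signal. Default none.
#' @param dialect `"english"` (default) or `"chinese"` (sentinel only).
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n = 2000, seed = 1, miss_rate = 0.3,
                             ph_rate = 0.4, beta = default_beta(),
                             beta0 = -0.9,
                             missingness_mode = c("informative", "MCAR"),
                             informative_factor = 0.25,
                             withhold_from_text = character(0),
                             dialect = "english") {
  missingness_mode <- match.arg(missingness_mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("generator_config: n must be >= 1")
  cats <- category_names()
  if (is.null(names(miss_rate))) {
    miss_rate <- setNames(rep_len(miss_rate, 10L), cats)
  } else {
    full <- setNames(rep(0, 10L), cats)
    unknown <- setdiff(names(miss_rate), cats)
    if (length(unknown) > 0L) stop("miss_rate names unknown: ",
                                   paste(unknown, collapse = ", "))
    full[names(miss_rate)] <- miss_rate
    miss_rate <- full
  }
  if (any(miss_rate < 0 | miss_rate > 1)) stop("miss_rate must lie in [0,1]")
  if (ph_rate < 0 || ph_rate > 1) stop("ph_rate must lie in [0,1]")
  if (informative_factor < 0 || informative_factor > 1) {
    stop("informative_factor must lie in [0,1]")
  }
  unknown <- setdiff(names(beta), names(label_features()))
  if (length(unknown) > 0L) {
    stop("beta references unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(beta)) || !is.finite(beta0)) stop("beta/beta0 must be finite")
  unknown <- setdiff(withhold_from_text, cats)
  if (length(unknown) > 0L) stop("withhold_from_text unknown: ",
                                 paste(unknown, collapse = ", "))
  structure(list(
    n = n, seed = as.integer(seed), miss_rate = miss_rate, ph_rate = ph_rate,
    beta = beta, beta0 = beta0, missingness_mode = missingness_mode,
    informative_factor = informative_factor,
    withhold_from_text = withhold_from_text,
    dialect = match.arg(dialect, c("english", "chinese"))
  ), class = "generator_config")
}

biopsy_leaning_terms <- function() {
  feats <- label_features()
  stats::na.omit(vapply(feats, function(f) f[["term"]], character(1)))
}

#' Draw one synthetic report record
#'
#' Uses the current RNG state (callers seed it; [generate_corpus()] does so
#' from `config$seed`). The latent descriptor of each category is drawn
#' uniformly from the lexicon; the label probability is
#' `plogis(beta0 + sum(beta[f] * active(f)))`; the free text realizes exactly
#' the categories drawn as present, one seeded template sentence each, plus
#' the optional personal-history clause; the structured half is the latent
#' map restricted to present categories (before any MCI completion).
#'
#' @param config A [generator_config()].
#' @param id Record identifier.
#' @param lexicon Lexicon to draw descriptors from.
#' @return A list with elements `truth` (latent map, presence map,
#'   `label_prob`, `label`, active features), `free`
#'   ([free_text_report()]) and `structured` ([structured_report()]).
#' @export
sample_record <- function(config, id = "r1", lexicon = default_lexicon()) {
  cats <- category_names()
  latent <- vapply(cats, function(cat_name) {
    terms <- lexicon[[cat_name]]$terms
    terms[[sample.int(length(terms), 1L)]]
  }, character(1))

  # personal history
  has_ph <- runif(1) < config$ph_rate
  ph_family <- ph_text <- NULL
  if (has_ph) {
    ph_family <- if (runif(1) < 0.5) "malignant" else "benign"
    pool <- ph_clauses()[[ph_family]]
    ph_text <- pool[[sample.int(length(pool), 1L)]]
  }

  # label model
  feats <- label_features()
  active <- vapply(names(feats), function(fname) {
    f <- feats[[fname]]
    if (fname == "ph_malignant") {
      isTRUE(ph_family == "malignant")
    } else {
      identical(unname(latent[[f[["category"]]]]), f[["term"]])
    }
  }, logical(1))
  beta_full <- setNames(numeric(length(feats)), names(feats))
  beta_full[names(config$beta)] <- config$beta
  label_prob <- plogis(config$beta0 + sum(beta_full * active))
  label <- rbinom(1, 1, label_prob)

  # per-category presence in the free text
  leaning <- biopsy_leaning_terms()
  miss <- config$miss_rate
  if (config$missingness_mode == "informative") {
    modulated <- unname(latent) %in% leaning
    miss[modulated] <- miss[modulated] * config$informative_factor
  }
  present <- runif(10L) >= miss
  names(present) <- cats
  text_present <- present & !(cats %in% config$withhold_from_text)

  # realize free text: one template sentence per mentioned category
  templates <- sentence_templates()
  sentences <- vapply(cats[text_present], function(cat_name) {
    tpl <- templates[[sample.int(length(templates), 1L)]]
    sub("{term}", latent[[cat_name]], tpl, fixed = TRUE)
  }, character(1))
  if (!is.null(ph_text)) sentences <- c(sentences, ph_text)
  if (length(sentences) == 0L) {
    sentences <- "Unremarkable bilateral breast examination"
  }
  text <- paste0(paste(sentences, collapse = ". "), ".")

  list(
    truth = list(latent = latent, present = present,
                 text_present = text_present, label_prob = label_prob,
                 label = label, features = active, ph_family = ph_family),
    free = free_text_report(id, text, personal_history = ph_text),
    structured = structured_report(latent[present])
  )
}

#' Generate a synthetic paired-report corpus
#'
#' Fully reproducible from `config$seed`; the records carry paired free-text
#' and structured halves plus the ground-truth latent state.
#'
#' @param config A [generator_config()].
#' @param lexicon Lexicon used for latent descriptors.
#' @return A list of class `"report_corpus"` with elements `records` (list of
#'   `list(free, structured, label)`), `truth` (per-record ground truth) and
#'   `config`.
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicon = default_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  draws <- lapply(seq_len(config$n), function(i) {
    sample_record(config, id = sprintf("rec%05d", i), lexicon = lexicon)
  })
  structure(list(
    records = lapply(draws, function(d) {
      list(free = d$free, structured = d$structured,
           label = d$truth$label)
    }),
    truth = lapply(draws, `[[`, "truth"),
    config = config
  ), class = "report_corpus")
}

#' @export
print.report_corpus <- function(x, ...) {
  labels <- vapply(x$records, `[[`, integer(1), "label")
  cat(sprintf("<report_corpus> %d records, P(biopsy)=%.3f, seed=%d\n",
              length(x$records), mean(labels), x$config$seed))
  invisible(x)
}

#' @export
length.report_corpus <- function(x) length(x$records)

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Train/test/validation split ratios
#'
#' @param train,test,val Positive fractions summing to 1 (within 1e-9).
#'   Defaults 0.70 / 0.20 / 0.10.
#' @return Validated list of class `"split_ratios"`.
#' @export
split_ratios <- function(train = 0.70, test = 0.20, val = 0.10) {
  if (train <= 0 || test <= 0 || val <= 0) stop("split fractions must be positive")
  if (abs(train + test + val - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(train = train, test = test, val = val), class = "split_ratios")
}

#' Deterministic split sizes under the floor-remainder rule
#'
#' `|val| = floor(val * N)`, `|test| = floor(test * N)`, the remainder goes to
#' the training set — the rule consistent with a 70/20/10 split of 11,884
#' records giving 8320 / 2376 / 1188.
#'
#' @param n Total record count.
#' @param ratios A [split_ratios()].
#' @return Named integer vector `c(train, test, val)`.
#' @export
#' @examples
#' split_sizes(11884)   # 8320 2376 1188
split_sizes <- function(n, ratios = split_ratios()) {
  n <- as.integer(n)
  n_val <- as.integer(floor(ratios$val * n))
  n_test <- as.integer(floor(ratios$test * n))
  c(train = n - n_val - n_test, test = n_test, val = n_val)
}

#' Randomly split a corpus into train/test/validation sets
#'
#' A seeded uniform permutation assigns records to record-disjoint splits
#' whose union is the input; sizes follow [split_sizes()].
#'
#' @param corpus A `report_corpus` (or plain list of records).
#' @param ratios A [split_ratios()].
#' @param seed Seed of the permutation.
#' @return List with elements `train`, `test`, `val` (lists of records; when
#'   a `report_corpus` is supplied the ground truth is split alongside and
#'   each part is returned as a `report_corpus`), plus `indices` with the
#'   permutation assignment.
#' @export
split_dataset <- function(corpus, ratios = split_ratios(), seed = 1) {
  records <- if (inherits(corpus, "report_corpus")) corpus$records else corpus
  n <- length(records)
  if (n == 0L) stop("cannot split an empty dataset")
  sizes <- split_sizes(n, ratios)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(
    train = sort(perm[seq_len(sizes[["train"]])]),
    test  = sort(perm[sizes[["train"]] + seq_len(sizes[["test"]])]),
    val   = if (sizes[["val"]] > 0L) {
      sort(perm[sizes[["train"]] + sizes[["test"]] + seq_len(sizes[["val"]])])
    } else integer(0)
  )
  take <- function(i) {
    if (inherits(corpus, "report_corpus")) {
      structure(list(records = corpus$records[i], truth = corpus$truth[i],
                     config = corpus$config), class = "report_corpus")
    } else {
      records[i]
    }
  }
  list(train = take(idx$train), test = take(idx$test), val = take(idx$val),
       indices = idx)
}

#' Mutual information between missingness and the label
#'
#' Plug-in estimate of the summed per-category mutual information (in nats)
#' between each category's missingness indicator and the binary label, with a
#' permutation test of the null that missingness is uninformative.
#'
#' @param corpus A `report_corpus`.
#' @param n_perm Number of label permutations for the test.
#' @return List with `mi` (observed summed MI), `p_value` and the permutation
#'   distribution.
#' @export
missingness_label_mi <- function(corpus, n_perm = 200) {
  stopifnot(inherits(corpus, "report_corpus"))
  miss <- t(vapply(corpus$truth, function(t) !t$present, logical(10)))
  labels <- vapply(corpus$truth, `[[`, integer(1), "label")
  mi_of <- function(y) {
    sum(apply(miss, 2, function(m) {
      tab <- table(factor(m, c(FALSE, TRUE)), factor(y, 0:1))
      p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p)
      s <- 0
      for (i in 1:2) for (j in 1:2) {
        if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
      }
      s
    }))
  }
  observed <- mi_of(labels)
  perm <- vapply(seq_len(n_perm), function(i) mi_of(sample(labels)), numeric(1))
  list(mi = observed, p_value = (1 + sum(perm >= observed)) / (1 + n_perm),
       perm = perm)
}
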