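# Liability-threshold synthetic EHR generator. Latent factor scores are drawn
# from MVN(0, Phi), mapped through standardized loadings Lambda, combined with
# (possibly correlated) unique parts, and thresholded at qnorm(1 - prevalence)
# to produce lifetime diagnosis indicators. Raw codes, event dates, and
# external correlates are layered on top so the ingestion and validation
# stages can be exercised end to end.

# deterministic sub-stream seeds so components can be regenerated independently
stream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) + k * 1000003L
}

#' Generator configuration for the liability-threshold simulator
#'
#' Builds and validates the configuration driving [simulate_dataset()]. The
#' liability scale is standardized: each diagnosis's implied variance is
#' `Lambda_j Phi Lambda_j' + uniqueness_j = 1`, with the uniqueness solved
#' from the loadings (and required to be non-negative), so loadings are
#' interpretable as standardized.
#'
#' @param n_persons Number of persons to simulate.
#' @param loadings `d x q` matrix of standardized loadings (rows = diagnoses,
#'   with rownames; columns = factors, with colnames).
#' @param factor_corr `q x q` factor correlation matrix (unit diagonal, PSD).
#' @param prevalences Named per-diagnosis lifetime prevalence, strictly in
#'   (0, 1).
#' @param residual_corr Optional tibble of uniqueness-level correlated
#'   residual pairs with columns `a`, `b`, `value`: `value` is the increment
#'   to the implied liability correlation of the pair.
#' @param correlate_effects Optional tibble describing external correlates,
#'   columns `correlate`, `type` (`"continuous"`, `"binary"`, `"ordinal"`),
#'   `noise_var`, and one `beta_<factor>` column per factor (regression
#'   weights of the correlate's latent on the factor scores). Ordinal
#'   correlates also use `n_levels`.
#' @param seed Integer seed; all sub-draws derive from counter-based
#'   sub-streams of it.
#' @param codes_per_diagnosis Upper bound of raw-code variants emitted per
#'   diagnosis cluster (multiplicity drawn uniformly from 1..4 per event).
#' @param date_window Character vector of two ISO dates bounding event dates.
#' @return An object of class `generator_config` (validated list).
#' @export
generator_config <- function(n_persons, loadings, factor_corr, prevalences,
                             residual_corr = NULL, correlate_effects = NULL,
                             seed = 1L, codes_per_diagnosis = 4L,
                             date_window = c("2018-01-01", "2022-12-31")) {
  stopifnot(is.matrix(loadings), is.matrix(factor_corr))
  d <- nrow(loadings); q <- ncol(loadings)
  if (is.null(rownames(loadings)))
    rownames(loadings) <- paste0("dx", seq_len(d))
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("F", seq_len(q))
  if (n_persons < 1) stop("n_persons must be positive", call. = FALSE)
  if (!isTRUE(all.equal(unname(diag(factor_corr)), rep(1, q))))
    stop("factor_corr must have unit diagonal", call. = FALSE)
  ev <- eigen((factor_corr + t(factor_corr)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("factor_corr is not positive semi-definite (eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (any(rowSums(abs(loadings)) == 0))
    stop("every diagnosis needs at least one nonzero loading", call. = FALSE)
  communality <- rowSums((loadings %*% factor_corr) * loadings)
  uniqueness <- 1 - communality
  if (any(uniqueness < -1e-10)) {
    bad <- rownames(loadings)[which.min(uniqueness)]
    stop(sprintf("negative uniqueness for diagnosis '%s' (%.4f)",
                 bad, min(uniqueness)), call. = FALSE)
  }
  prevalences <- prevalences[rownames(loadings)]
  if (anyNA(prevalences) || any(prevalences <= 0) || any(prevalences >= 1))
    stop("prevalences must be named for every diagnosis and lie strictly in (0,1)",
         call. = FALSE)
  if (!is.null(residual_corr)) {
    residual_corr <- tibble::as_tibble(residual_corr)
    stopifnot(all(c("a", "b", "value") %in% names(residual_corr)))
    missing_dx <- setdiff(c(residual_corr$a, residual_corr$b),
                          rownames(loadings))
    if (length(missing_dx))
      stop("residual_corr names unknown diagnoses: ",
           paste(missing_dx, collapse = ", "), call. = FALSE)
  }
  if (!is.null(correlate_effects)) {
    correlate_effects <- tibble::as_tibble(correlate_effects)
    stopifnot(all(c("correlate", "type", "noise_var") %in%
                    names(correlate_effects)))
    beta_cols <- paste0("beta_", colnames(loadings))
    if (!all(beta_cols %in% names(correlate_effects)))
      stop("correlate_effects needs one beta_<factor> column per factor",
           call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons), loadings = loadings,
         factor_corr = factor_corr, prevalences = prevalences,
         uniqueness = stats::setNames(pmax(uniqueness, 0), rownames(loadings)),
         residual_corr = residual_corr, correlate_effects = correlate_effects,
         seed = as.integer(seed),
         codes_per_diagnosis = as.integer(codes_per_diagnosis),
         date_window = date_window),
    class = "generator_config")
}

# implied tetrachoric matrix Lambda Phi Lambda' + residual increments,
# unit diagonal
implied_tetrachoric <- function(config) {
  S <- config$loadings %*% config$factor_corr %*% t(config$loadings)
  if (!is.null(config$residual_corr)) {
    for (r in seq_len(nrow(config$residual_corr))) {
      a <- config$residual_corr$a[r]; b <- config$residual_corr$b[r]
      S[a, b] <- S[a, b] + config$residual_corr$value[r]
      S[b, a] <- S[a, b]
    }
  }
  diag(S) <- 1
  S
}

#' Simulate an EHR-like diagnosis dataset from a liability-threshold model
#'
#' Draws factor scores from `MVN(0, Phi)`, forms standardized liabilities
#' `Lambda f + sqrt(uniqueness) e` (with correlated unique parts injected via
#' shared standard-normal components for the configured residual pairs), and
#' sets `diagnosis = 1` when the liability exceeds `qnorm(1 - prevalence)`.
#' Each positive diagnosis is emitted as 1-4 raw codes drawn from that
#' cluster's code list, with uniform event dates. External correlates are
#' generated from the configured linear model on the factor scores. Persons
#' with no diagnosis are retained (the cohort filter downstream removes them).
#'
#' @param config A [generator_config()].
#' @param events Emit the long raw-code event table (default `TRUE`); disable
#'   for speed when only the binary matrix is needed.
#' @return A list with elements `diagnoses` (tibble: `person_id` + one 0/1
#'   column per diagnosis), `events` (tibble: `person_id`, `raw_code`,
#'   `event_date`), `cluster_map` (tibble: `raw_code`, `diagnosis_label`,
#'   `diagnosis_index`), `correlates` (long tibble: `person_id`, `correlate`,
#'   `value`, `type`), and `truth` (class `synthetic_truth`: the resolved
#'   config plus thresholds `tau`, the implied tetrachoric matrix, and the
#'   true factor scores).
#' @export
simulate_dataset <- function(config, events = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  d <- nrow(config$loadings); q <- ncol(config$loadings)
  n <- config$n_persons
  labels <- rownames(config$loadings)
  tau <- stats::qnorm(1 - config$prevalences)

  # factor scores ~ MVN(0, Phi)
  set.seed(stream_seed(config$seed, 1L))
  ch <- chol_psd(config$factor_corr)
  fs <- matrix(stats::rnorm(n * q), n, q) %*% ch
  colnames(fs) <- colnames(config$loadings)

  # unique parts with shared components for residual pairs
  set.seed(stream_seed(config$seed, 2L))
  E <- matrix(stats::rnorm(n * d), n, d)
  alloc <- rep(0, d); names(alloc) <- labels
  if (!is.null(config$residual_corr) && nrow(config$residual_corr)) {
    rc <- config$residual_corr
    u <- config$uniqueness
    a_pair <- rc$value / sqrt(u[rc$a] * u[rc$b])  # unique-part correlation
    if (any(a_pair < 0))
      stop("negative residual correlations are not supported by the shared-component construction",
           call. = FALSE)
    shared <- matrix(stats::rnorm(n * nrow(rc)), n, nrow(rc))
    contrib <- matrix(0, n, d, dimnames = list(NULL, labels))
    for (p in seq_len(nrow(rc))) {
      for (dx in c(rc$a[p], rc$b[p])) {
        alloc[dx] <- alloc[dx] + a_pair[p]
        contrib[, dx] <- contrib[, dx] + sqrt(a_pair[p]) * shared[, p]
      }
    }
    if (any(alloc > 1))
      stop("residual correlations allocate more than the available uniqueness for: ",
           paste(names(alloc)[alloc > 1], collapse = ", "), call. = FALSE)
    E <- sweep(E, 2, sqrt(1 - alloc), "*") + contrib
  }

  liab <- fs %*% t(config$loadings) +
    sweep(E, 2, sqrt(config$uniqueness), "*")
  Y <- matrix(as.double(sweep(liab, 2, tau, ">")), n, d,
              dimnames = list(NULL, labels))
  person_id <- sprintf("P%06d", seq_len(n))
  diagnoses <- tibble::tibble(person_id = person_id)
  diagnoses <- dplyr::bind_cols(diagnoses, tibble::as_tibble(Y))

  cluster_map <- build_cluster_map(labels, config$codes_per_diagnosis)

  ev_tbl <- NULL
  if (events) {
    set.seed(stream_seed(config$seed, 4L))
    pos <- which(Y == 1, arr.ind = TRUE)
    n_codes <- sample.int(4L, nrow(pos), replace = TRUE)
    pid <- rep(person_id[pos[, 1]], n_codes)
    dx_idx <- rep(pos[, 2], n_codes)
    code_lists <- split(cluster_map$raw_code, cluster_map$diagnosis_index)
    per_dx_n <- lengths(code_lists)
    raw <- vapply(dx_idx, function(k)
      code_lists[[k]][sample.int(per_dx_n[k], 1L)], character(1))
    day0 <- as.Date(config$date_window[1])
    span <- as.integer(as.Date(config$date_window[2]) - day0)
    dates <- day0 + sample.int(span + 1L, length(pid), replace = TRUE) - 1L
    ev_tbl <- tibble::tibble(person_id = pid, raw_code = raw,
                             event_date = as.character(dates))
    ev_tbl <- dplyr::arrange(ev_tbl, .data$person_id, .data$event_date,
                             .data$raw_code)
  }

  correlates <- NULL
  if (!is.null(config$correlate_effects)) {
    set.seed(stream_seed(config$seed, 3L))
    ce <- config$correlate_effects
    beta_cols <- paste0("beta_", colnames(config$loadings))
    rows <- vector("list", nrow(ce))
    for (i in seq_len(nrow(ce))) {
      w <- as.numeric(ce[i, beta_cols])
      latent <- as.vector(fs %*% w) +
        sqrt(ce$noise_var[i]) * stats::rnorm(n)
      value <- switch(ce$type[i],
        continuous = latent,
        binary = as.double(latent > 0),
        ordinal = {
          k <- if ("n_levels" %in% names(ce) && !is.na(ce$n_levels[i]))
            ce$n_levels[i] else 5L
          cuts <- stats::quantile(latent, probs = seq_len(k - 1) / k)
          as.double(findInterval(latent, cuts) + 1L)
        },
        stop("unknown correlate type: ", ce$type[i], call. = FALSE))
      rows[[i]] <- tibble::tibble(person_id = person_id,
                                  correlate = ce$correlate[i],
                                  value = value, type = ce$type[i])
    }
    correlates <- dplyr::bind_rows(rows)
  }

  truth <- structure(
    list(config = config, tau = tau,
         implied = implied_tetrachoric(config),
         factor_scores = tibble::as_tibble(fs) |>
           dplyr::mutate(person_id = person_id, .before = 1)),
    class = "synthetic_truth")

  list(diagnoses = diagnoses, events = ev_tbl, cluster_map = cluster_map,
       correlates = correlates, truth = truth)
}

# Cholesky-like factor tolerant of PSD (rank-deficient) inputs
chol_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(vals) * t(e$vectors)))
}

# synthetic raw-code variants per diagnosis cluster (1..codes_per variants)
build_cluster_map <- function(labels, codes_per = 4L) {
  known <- list(
    "autism spectrum disorder" = c("autism spectrum disorder", "autism",
                                   "autistic disorder", "Asperger syndrome"),
    "major depressive disorder" = c("major depressive disorder",
                                    "major depression",
                                    "recurrent depressive disorder"),
    "schizophrenia" = c("schizophrenia", "paranoid schizophrenia",
                        "undifferentiated schizophrenia"))
  rows <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    codes <- if (lab %in% names(known)) known[[lab]]
             else c(lab, paste0(lab, " [variant ", seq_len(codes_per - 1L), "]"))
    tibble::tibble(raw_code = codes, diagnosis_label = lab,
                   diagnosis_index = i - 1L)
  })
  dplyr::bind_rows(rows)
}

#' Six-factor preset generator configuration
#'
#' A 39-diagnosis, six-factor configuration emulating the broad structure of
#' lifetime psychiatric comorbidity: Fear, Distress, Externalizing, Substance
#' Use, Thought Problems, and Neurodevelopmental dimensions with 6-7
#' diagnoses each (every factor size within 5-8). Diagnosis labels use
#' well-known disorders plus labelled synthetic placeholders to reach 39.
#' Loadings lie in \[0.4, 0.8\] (lower on Fear and Distress), the
#' Fear-Distress factor correlation is high (0.9), and uniqueness-level
#' correlated residuals are preset for (schizophrenia, schizoaffective),
#' (OCD, OCPD), (MDD, dysthymia) and among the ADHD subtypes. External
#' correlates mirror a demographic/clinical mix: a binary sex analog, a
#' continuous sleep-disturbance score, and ordinal income and education
#' analogs.
#'
#' @param n_persons Cohort size (default 20000).
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
six_factor_preset <- function(n_persons = 20000, seed = 1L) {
  factors <- list(
    Fear = c("agoraphobia", "panic disorder", "obsessive-compulsive disorder",
             "obsessive-compulsive personality disorder", "specific phobia",
             "social anxiety disorder", "separation anxiety disorder"),
    Distress = c("major depressive disorder", "dysthymia",
                 "generalized anxiety disorder", "PTSD",
                 "adjustment disorder", "eating disorder",
                 "somatic symptom disorder"),
    Externalizing = c("conduct disorder", "oppositional defiant disorder",
                      "ADHD-HI", "intermittent explosive disorder",
                      "impulse control disorder", "borderline personality disorder"),
    SubstanceUse = c("alcohol use disorder", "opioid use disorder",
                     "cannabis use disorder", "stimulant use disorder",
                     "antisocial personality disorder", "nicotine dependence"),
    ThoughtProblems = c("schizophrenia", "schizoaffective disorder",
                        "delusional disorder", "psychotic disorder NOS",
                        "bipolar I disorder", "schizotypal personality disorder"),
    Neurodevelopmental = c("ADHD-C", "ADHD-IN", "autism spectrum disorder",
                           "tic disorder", "Tourette syndrome",
                           "learning disorder", "intellectual disability"))
  labels <- unlist(factors, use.names = FALSE)
  stopifnot(length(labels) == 39, !anyDuplicated(labels))
  q <- length(factors)
  d <- length(labels)

  Lambda <- matrix(0, d, q, dimnames = list(labels, names(factors)))
  # deterministic within-factor loading ladders; Fear/Distress run lower
  ranges <- list(Fear = c(0.42, 0.56), Distress = c(0.44, 0.58),
                 Externalizing = c(0.58, 0.76), SubstanceUse = c(0.60, 0.78),
                 ThoughtProblems = c(0.58, 0.80), Neurodevelopmental = c(0.56, 0.74))
  for (f in names(factors)) {
    k <- length(factors[[f]])
    Lambda[factors[[f]], f] <- seq(ranges[[f]][2], ranges[[f]][1],
                                   length.out = k)
  }

  Phi <- matrix(c(
    1.00, 0.90, 0.45, 0.35, 0.40, 0.40,
    0.90, 1.00, 0.50, 0.40, 0.45, 0.40,
    0.45, 0.50, 1.00, 0.45, 0.45, 0.50,
    0.35, 0.40, 0.45, 1.00, 0.40, 0.35,
    0.40, 0.45, 0.45, 0.40, 1.00, 0.40,
    0.40, 0.40, 0.50, 0.35, 0.40, 1.00), q, q,
    dimnames = list(names(factors), names(factors)))

  # lifetime EHR-style prevalences, 0.05-0.35, higher for mood/anxiety
  prev_ranges <- list(Fear = c(0.08, 0.20), Distress = c(0.12, 0.35),
                      Externalizing = c(0.06, 0.15), SubstanceUse = c(0.07, 0.22),
                      ThoughtProblems = c(0.05, 0.12),
                      Neurodevelopmental = c(0.05, 0.14))
  prevalences <- stats::setNames(numeric(d), labels)
  for (f in names(factors)) {
    k <- length(factors[[f]])
    prevalences[factors[[f]]] <- seq(prev_ranges[[f]][2], prev_ranges[[f]][1],
                                     length.out = k)
  }

  residual_corr <- tibble::tribble(
    ~a, ~b, ~value,
    "schizophrenia", "schizoaffective disorder", 0.15,
    "obsessive-compulsive disorder", "obsessive-compulsive personality disorder", 0.15,
    "major depressive disorder", "dysthymia", 0.15,
    "ADHD-C", "ADHD-HI", 0.10,
    "ADHD-C", "ADHD-IN", 0.10,
    "ADHD-HI", "ADHD-IN", 0.10)

  correlate_effects <- tibble::tibble(
    correlate = c("male_sex", "sleep_disturbance", "income", "education"),
    type = c("binary", "continuous", "ordinal", "ordinal"),
    noise_var = c(1, 1, 1, 1),
    n_levels = c(NA, NA, 5L, 4L),
    beta_Fear = c(-0.20, 0.10, 0.00, 0.00),
    beta_Distress = c(-0.30, 0.50, -0.10, -0.05),
    beta_Externalizing = c(0.25, 0.40, -0.15, -0.15),
    beta_SubstanceUse = c(0.30, -0.90, -0.40, -0.35),
    beta_ThoughtProblems = c(0.00, 0.10, -0.20, -0.15),
    beta_Neurodevelopmental = c(0.15, 0.05, -0.10, -0.10))

  generator_config(n_persons = n_persons, loadings = Lambda,
                   factor_corr = Phi, prevalences = prevalences,
                   residual_corr = residual_corr,
                   correlate_effects = correlate_effects, seed = seed)
}

#' Model text matching a generator configuration
#'
#' Writes the factor-model mini-language specification corresponding to a
#' generator configuration's loading pattern and residual pairs, for use as
#' the matched (true) model in recovery studies.
#'
#' @param config A [generator_config()].
#' @return A single string parseable by [parse_model()].
#' @export
config_model_text <- function(config) {
  L <- config$loadings
  lines <- character(0)
  for (f in colnames(L)) {
    members <- rownames(L)[L[, f] != 0]
    lines <- c(lines, paste0(f, " =~ ", paste(members, collapse = " + ")))
  }
  if (!is.null(config$residual_corr) && nrow(config$residual_corr)) {
    lines <- c(lines, paste0(config$residual_corr$a, " ~~ ",
                             config$residual_corr$b))
  }
  paste(lines, collapse = "\n")
}
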