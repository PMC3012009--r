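#' Describe a synthetic expression cohort
#'
#' A cohort design captures the statistical structure the analysis stack
#' assumes: several tumor subtypes of unequal size plus matched normal
#' tissue, gene-wise variance heterogeneity drawn from a scaled inverse
#' chi-square prior, subtype marker programs, planted chromosome-arm
#' shifts (expression dosage of copy-number events), planted gene-set
#' activations, and an optional driver gene whose expression is coupled to
#' a target set's activation.
#'
#' Defaults mirror the renal-tumor study design the package is built
#' around: three tumor subtypes of 6, 11 and 12 samples with 12 matched
#' normals from one tissue; one subtype carries an OXPHOS-like gene-set
#' activation while the others carry arm-level losses; a driver gene is
#' negatively coupled (target Spearman rho of -0.6) to the activated set.
#'
#' @param n_genes Number of genes; spread evenly over chromosome arms.
#' @param chromosomes Data frame with columns `chromosome`, `p_length`,
#'   `q_length` (base pairs).  Default: five 220 Mb chromosomes.
#' @param subtypes List of subtype specs, each a list with `label`,
#'   `n_samples`, `arm_events` (list of `list(chromosome, arm, shift,
#'   penetrance)`, `arm` one of `"p"`, `"q"`, `"both"`) and `set_events`
#'   (list of `list(set, shift)`).
#' @param n_normals Number of normal samples of `tissue`.
#' @param tissue Tissue label shared by all samples.
#' @param d0_true,s0sq_true Variance prior: per-gene true variances are
#'   drawn as `s0sq_true * d0_true / rchisq(d0_true)`; `d0_true = Inf`
#'   gives a common variance `s0sq_true`.
#' @param mu0,sd0 Baseline log2 mean expression distribution (Normal).
#' @param n_marker_genes,marker_shift Each subtype receives a private
#'   marker program of `n_marker_genes` genes shifted by around
#'   `marker_shift` log2 units (random sign), emulating the broad
#'   subtype-specific expression programs real tumor subtypes show.  Set
#'   `n_marker_genes = 0` for exchangeable (null) cohorts.
#' @param planted_sets List of planted pathway specs: `list(name, size)`
#'   plus optional `overlap_with`, `n_overlap` to share members with an
#'   earlier planted set.
#' @param n_random_sets,random_set_size Decoy pathway sets with random
#'   membership.
#' @param coupling `NULL`, or a list with `target_set`, `rho_target`
#'   (in `[-0.99, 0.99]`), `activation_sd` (per-sample spread of the
#'   target set's activation), `driver_noise_sd`, and optionally
#'   `driver_gene` (default: first gene outside all planted sets).
#' @param replicates `NULL`, or `list(sample = <id or NULL>, n_reps = k)`
#'   to emit `k` technical replicate columns of one tumor sample (default:
#'   the first tumor), sharing its biological signal with independent
#'   measurement noise.
#' @param seed Mandatory integer seed; all randomness derives from it
#'   through labelled sub-streams (see [derive_seed()]).
#' @return A list of class `CohortDesign`.
#' @seealso [simulate_cohort()], [fixture_small()]
#' @export
cohort_design <- function(n_genes = 5000,
                          chromosomes = NULL,
                          subtypes = NULL,
                          n_normals = 12,
                          tissue = "kidney",
                          d0_true = 4, s0sq_true = 0.09,
                          mu0 = 8, sd0 = 1.5,
                          n_marker_genes = 300, marker_shift = 1.0,
                          planted_sets = NULL,
                          n_random_sets = 30, random_set_size = 50,
                          coupling = NULL,
                          replicates = NULL,
                          seed) {
  if (missing(seed)) abort("cohort_design() requires an explicit 'seed'")
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(chromosome = paste0("chr", 1:5),
                              p_length = 1e8, q_length = 1.2e8,
                              stringsAsFactors = FALSE)
  }
  if (is.null(subtypes)) {
    subtypes <- list(
      list(label = "BHD", n_samples = 6,
           arm_events = list(),
           set_events = list(list(set = "OXPHOS_LIKE", shift = 0.8))),
      list(label = "ON", n_samples = 11,
           arm_events = list(list(chromosome = "chr1", arm = "both",
                                  shift = -0.5, penetrance = 0.5)),
           set_events = list()),
      list(label = "CH", n_samples = 12,
           arm_events = list(list(chromosome = "chr1", arm = "both",
                                  shift = -0.5, penetrance = 0.9),
                             list(chromosome = "chr2", arm = "both",
                                  shift = -0.5, penetrance = 0.9)),
           set_events = list())
    )
  }
  if (is.null(planted_sets)) {
    planted_sets <- list(
      list(name = "OXPHOS_LIKE", size = 100),
      list(name = "PGC_LIKE", size = 80,
           overlap_with = "OXPHOS_LIKE", n_overlap = 40)
    )
  }
  if (is.null(coupling)) {
    coupling <- if ("OXPHOS_LIKE" %in% vapply(planted_sets, `[[`, "", "name"))
      list(driver_gene = NULL, target_set = "OXPHOS_LIKE",
           rho_target = -0.6, activation_sd = 0.3, driver_noise_sd = 0.3)
    else NULL
  } else if (identical(coupling, "none") || identical(coupling, NA)) {
    coupling <- NULL
  }
  design <- list(n_genes = n_genes, chromosomes = chromosomes,
                 subtypes = subtypes, n_normals = n_normals, tissue = tissue,
                 d0_true = d0_true, s0sq_true = s0sq_true,
                 mu0 = mu0, sd0 = sd0,
                 n_marker_genes = n_marker_genes, marker_shift = marker_shift,
                 planted_sets = planted_sets,
                 n_random_sets = n_random_sets,
                 random_set_size = random_set_size,
                 coupling = coupling, replicates = replicates,
                 seed = as.integer(seed))
  validate_design(design)
  structure(design, class = "CohortDesign")
}

validate_design <- function(d) {
  if (d$n_genes < 2L) abort("n_genes must be >= 2")
  set_names <- c(vapply(d$planted_sets, `[[`, "", "name"))
  if (anyDuplicated(set_names)) abort("duplicated planted set names")
  for (st in d$subtypes) {
    if (is.null(st$label) || is.null(st$n_samples) || st$n_samples < 1L)
      abort("each subtype needs a label and n_samples >= 1")
    for (ev in st$arm_events %||% list()) {
      if (ev$penetrance < 0 || ev$penetrance > 1)
        abort("penetrance must lie in [0, 1] (subtype '%s')", st$label)
      if (!ev$chromosome %in% d$chromosomes$chromosome)
        abort("arm event on unknown chromosome '%s' (subtype '%s')",
              ev$chromosome, st$label)
      if (!ev$arm %in% c("p", "q", "both"))
        abort("arm must be 'p', 'q' or 'both' (subtype '%s')", st$label)
    }
    for (ev in st$set_events %||% list()) {
      if (!ev$set %in% set_names)
        abort("set event names unknown set '%s' (subtype '%s'); planted sets are: %s",
              ev$set, st$label, quote_ids(set_names))
    }
  }
  if (!is.null(d$coupling)) {
    if (!d$coupling$target_set %in% set_names)
      abort("coupling target set '%s' is not a planted set", d$coupling$target_set)
    if (abs(d$coupling$rho_target) > 0.99)
      abort("|rho_target| must be <= 0.99")
  }
  invisible(d)
}

# gene placement: even spacing along each arm, wholly inside the arm
place_genes <- function(design) {
  chr <- design$chromosomes
  n_arms <- 2L * nrow(chr)
  per_arm <- rep(design$n_genes %/% n_arms, n_arms)
  extra <- design$n_genes %% n_arms
  if (extra > 0L) per_arm[seq_len(extra)] <- per_arm[seq_len(extra)] + 1L
  cen_width <- 2e6
  ann <- vector("list", n_arms)
  bands <- vector("list", nrow(chr))
  k <- 0L; gi <- 0L
  for (i in seq_len(nrow(chr))) {
    plen <- chr$p_length[i]; qlen <- chr$q_length[i]
    q0 <- plen + cen_width
    bands[[i]] <- data.frame(
      chromosome = chr$chromosome[i],
      start = c(0, plen, plen + cen_width / 2, q0),
      end = c(plen, plen + cen_width / 2, q0, q0 + qlen),
      band = c("p11", "p11.1", "q11.1", "q11"),
      stain = c("gneg", "acen", "acen", "gneg"),
      stringsAsFactors = FALSE)
    for (arm in c("p", "q")) {
      k <- k + 1L
      n <- per_arm[k]
      if (n == 0L) next
      alen <- if (arm == "p") plen else qlen
      offset <- if (arm == "p") 0 else q0
      spacing <- floor(alen / n)
      width <- max(1, min(1e4, spacing - 1))
      starts <- offset + (seq_len(n) - 1L) * spacing
      ann[[k]] <- data.frame(
        gene_id = sprintf("g%05d", gi + seq_len(n)),
        chromosome = chr$chromosome[i],
        start = starts, end = starts + width,
        strand = rep_len(c("+", "-"), n), arm = arm,
        stringsAsFactors = FALSE)
      gi <- gi + n
    }
  }
  list(annotation = gene_annotation(do.call(rbind, ann)),
       cytoband = do.call(rbind, bands))
}

#' Simulate an expression cohort with known ground truth
#'
#' Generates, from a [cohort_design()], an absolute-space log2 expression
#' matrix plus the sample sheet, gene annotation, cytoband table and gene
#' set collection that describe it, together with a `truth` record of every
#' planted structure.  The generative model for gene `g` in sample `j` is
#'
#' \deqn{y_{gj} = \mu_g + marker_{g,subtype(j)} + set shift + arm shift +
#'       \epsilon_{gj}, \quad \epsilon_{gj} \sim N(0, \sigma_g^2)}
#'
#' with \eqn{\mu_g \sim N(\mu_0, sd_0^2)} and \eqn{\sigma_g^2} from the
#' scaled inverse chi-square prior.  Arm events are drawn per tumor sample
#' with the event's penetrance; normals never carry events.  The coupling
#' target set receives a continuous per-sample activation
#' \eqn{A_j = shift_{subtype(j)} + N(0, activation\_sd^2)} shared by its
#' member genes, and the driver gene's expression is constructed around
#' \eqn{A_j} so that its Spearman correlation with the set's activation
#' approximates `rho_target`.
#'
#' The output is bit-reproducible from `design$seed`; each generation stage
#' draws from its own labelled sub-stream so stages can be regenerated
#' independently.
#'
#' @param design A [cohort_design()].
#' @return A list of class `SyntheticCohort` with elements `expression`
#'   (`ExpressionMatrix`, absolute space), `sheet`, `annotation`,
#'   `cytoband`, `sets` (`GeneSetCollection`), `truth` and `design`.
#' @export
simulate_cohort <- function(design) {
  validate_design(design)
  placed <- place_genes(design)
  ann <- placed$annotation
  genes <- ann$gene_id
  G <- length(genes)

  # baseline means and true gene variances
  base <- withr::with_seed(derive_seed(design$seed, "baseline"), {
    mu <- stats::rnorm(G, design$mu0, design$sd0)
    sigma2 <- if (is.infinite(design$d0_true)) rep(design$s0sq_true, G)
              else design$s0sq_true * design$d0_true /
                   stats::rchisq(G, df = design$d0_true)
    list(mu = mu, sigma2 = sigma2)
  })

  # gene sets: planted pathways, decoys, subtype marker programs
  setinfo <- withr::with_seed(derive_seed(design$seed, "sets"), {
    sets <- list()
    for (ps in design$planted_sets) {
      if (!is.null(ps$overlap_with)) {
        shared <- sample(sets[[ps$overlap_with]], ps$n_overlap)
        rest <- sample(setdiff(genes, sets[[ps$overlap_with]]),
                       ps$size - ps$n_overlap)
        sets[[ps$name]] <- sample(c(shared, rest))
      } else {
        sets[[ps$name]] <- sample(genes, ps$size)
      }
    }
    planted_names <- names(sets)
    if (design$n_random_sets > 0L) {
      for (i in seq_len(design$n_random_sets)) {
        sets[[sprintf("RANDOM_SET_%03d", i)]] <-
          sample(genes, min(design$random_set_size, G))
      }
    }
    planted_members <- unique(unlist(sets[planted_names]))
    driver <- NULL
    if (!is.null(design$coupling)) {
      driver <- design$coupling$driver_gene %||%
        setdiff(genes, planted_members)[1L]
      if (is.na(driver)) abort("no gene available to act as coupling driver")
    }
    markers <- list()
    if (design$n_marker_genes > 0L) {
      target <- if (!is.null(design$coupling))
        design$coupling$target_set else NA_character_
      excluded <- unique(c(if (!is.na(target)) sets[[target]], driver))
      pool <- setdiff(genes, excluded)
      for (st in design$subtypes) {
        g <- sample(pool, min(design$n_marker_genes, length(pool)))
        markers[[st$label]] <- data.frame(
          gene_id = g,
          shift = sample(c(-1, 1), length(g), replace = TRUE) *
                  stats::rnorm(length(g), design$marker_shift, 0.2),
          stringsAsFactors = FALSE)
      }
    }
    list(sets = sets, planted = planted_names, driver = driver,
         markers = markers)
  })

  # sample layout
  sheet_rows <- list()
  for (st in design$subtypes) {
    sheet_rows[[st$label]] <- data.frame(
      sample_id = sprintf("%s_%02d", st$label, seq_len(st$n_samples)),
      tissue = design$tissue, group = st$label, is_normal = FALSE,
      replicate_group = NA_character_, patient = NA_character_,
      stringsAsFactors = FALSE)
  }
  sheet_rows$NORMAL <- data.frame(
    sample_id = sprintf("%s_n%02d", design$tissue, seq_len(design$n_normals)),
    tissue = design$tissue, group = "NORMAL", is_normal = TRUE,
    replicate_group = NA_character_, patient = NA_character_,
    stringsAsFactors = FALSE)
  sheet <- do.call(rbind, sheet_rows)
  rownames(sheet) <- NULL

  # technical replicates: duplicate one tumor column's biological signal
  if (!is.null(design$replicates)) {
    n_reps <- design$replicates$n_reps %||% 2L
    target <- design$replicates$sample %||% sheet$sample_id[!sheet$is_normal][1L]
    if (!target %in% sheet$sample_id) abort("replicate sample '%s' unknown", target)
    idx <- which(sheet$sample_id == target)
    reps <- sheet[rep(idx, n_reps), , drop = FALSE]
    reps$sample_id <- sprintf("%s_r%d", target, seq_len(n_reps))
    reps$replicate_group <- target
    sheet <- rbind(sheet[seq_len(idx - 1L), ], reps,
                   sheet[-seq_len(idx), , drop = FALSE])
    rownames(sheet) <- NULL
    rep_of <- stats::setNames(rep(target, n_reps), reps$sample_id)
  } else {
    rep_of <- character(0)
  }
  samples <- sheet$sample_id
  S <- length(samples)
  # biological identity of each column (replicates share their source's draws)
  bio <- ifelse(samples %in% names(rep_of), rep_of[samples], samples)
  subtype_of <- stats::setNames(sheet$group, sheet$sample_id)

  # planted events: arm draws per biological sample, set activations
  target_set <- if (!is.null(design$coupling)) design$coupling$target_set else NA
  events <- withr::with_seed(derive_seed(design$seed, "events"), {
    arm_rows <- list()
    for (st in design$subtypes) {
      ids <- unique(bio[subtype_of[samples] == st$label])
      for (ev in st$arm_events %||% list()) {
        arms <- if (ev$arm == "both") c("p", "q") else ev$arm
        drawn <- stats::rbinom(length(ids), 1L, ev$penetrance) == 1L
        for (a in arms) {
          arm_rows[[length(arm_rows) + 1L]] <- data.frame(
            sample_id = ids, chromosome = ev$chromosome, arm = a,
            shift = ev$shift, drawn = drawn, stringsAsFactors = FALSE)
        }
      }
    }
    set_shift <- stats::setNames(numeric(length(samples)), samples)
    set_rows <- list()
    for (st in design$subtypes) {
      for (ev in st$set_events %||% list()) {
        set_rows[[length(set_rows) + 1L]] <- data.frame(
          subtype = st$label, set = ev$set, shift = ev$shift,
          stringsAsFactors = FALSE)
        if (identical(ev$set, target_set))
          set_shift[subtype_of[samples] == st$label] <- ev$shift
      }
    }
    activation <- NULL
    if (!is.null(design$coupling)) {
      a_bio <- stats::setNames(
        stats::rnorm(length(unique(bio)), 0, design$coupling$activation_sd),
        unique(bio))
      activation <- set_shift + a_bio[bio]
    }
    list(arm = if (length(arm_rows)) do.call(rbind, arm_rows) else NULL,
         sets = if (length(set_rows)) do.call(rbind, set_rows) else NULL,
         activation = activation)
  })

  # assemble the signal matrix
  signal <- matrix(base$mu, G, S, dimnames = list(genes, samples))
  for (lab in names(setinfo$markers)) {
    cols <- samples[subtype_of[samples] == lab]
    if (!length(cols)) next
    mk <- setinfo$markers[[lab]]
    ridx <- match(mk$gene_id, genes)
    signal[ridx, cols] <- signal[ridx, cols] + mk$shift
  }
  if (!is.null(events$sets)) {
    for (i in seq_len(nrow(events$sets))) {
      ev <- events$sets[i, ]
      if (identical(ev$set, target_set)) next  # applied via activation below
      cols <- samples[subtype_of[samples] == ev$subtype]
      ridx <- match(setinfo$sets[[ev$set]], genes)
      signal[ridx, cols] <- signal[ridx, cols] + ev$shift
    }
  }
  if (!is.null(events$activation)) {
    ridx <- match(setinfo$sets[[target_set]], genes)
    signal[ridx, ] <- signal[ridx, ] +
      matrix(events$activation, length(ridx), S, byrow = TRUE)
  }
  if (!is.null(events$arm)) {
    ev_drawn <- events$arm[events$arm$drawn, , drop = FALSE]
    for (i in seq_len(nrow(ev_drawn))) {
      ev <- ev_drawn[i, ]
      ridx <- which(ann$chromosome == ev$chromosome & ann$arm == ev$arm)
      cols <- samples[bio == ev$sample_id]
      signal[ridx, cols] <- signal[ridx, cols] + ev$shift
    }
  }

  # measurement noise
  noise <- withr::with_seed(derive_seed(design$seed, "noise"), {
    matrix(stats::rnorm(G * S, 0, rep(sqrt(base$sigma2), S)), G, S)
  })
  values <- signal + noise

  # driver gene coupled to the target set's activation
  coupling_truth <- NULL
  if (!is.null(design$coupling)) {
    a <- events$activation
    rho_p <- 2 * sin(pi * abs(design$coupling$rho_target) / 6)
    sd_a <- stats::sd(a)
    beta <- if (sd_a > 0)
      sign(design$coupling$rho_target) * rho_p / sqrt(1 - rho_p^2) *
        design$coupling$driver_noise_sd / sd_a else 0
    drv <- match(setinfo$driver, genes)
    values[drv, ] <- withr::with_seed(derive_seed(design$seed, "coupling"), {
      base$mu[drv] + beta * (a - mean(a)) +
        stats::rnorm(S, 0, design$coupling$driver_noise_sd)
    })
    coupling_truth <- list(driver_gene = setinfo$driver,
                           target_set = target_set,
                           rho_target = design$coupling$rho_target,
                           beta = beta)
  }

  sets <- gene_set_collection(setinfo$sets, source = "synthetic")
  truth <- list(mu = stats::setNames(base$mu, genes),
                sigma2 = stats::setNames(base$sigma2, genes),
                markers = setinfo$markers,
                arm_events = events$arm,
                set_events = events$sets,
                activation = if (!is.null(events$activation))
                  stats::setNames(events$activation, samples) else NULL,
                coupling = coupling_truth,
                planted_sets = setinfo$planted)
  structure(list(expression = expression_matrix(values, "absolute"),
                 sheet = sample_sheet(sheet),
                 annotation = ann,
                 cytoband = placed$cytoband,
                 sets = sets,
                 truth = truth,
                 design = design),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d genes x %d samples, %d gene sets, seed %d\n",
              nrow(x$expression$values), ncol(x$expression$values),
              length(x$sets), x$design$seed))
  invisible(x)
}

#' Canonical small test cohort
#'
#' A deterministic cohort of 200 genes and 19 sample columns (three tumor
#' subtypes of 4, 5 and 4 samples, 5 normals, plus one technical replicate
#' pair): subtype `A` carries a `PATHWAY_A` activation coupled to a driver
#' gene at rho -0.6, subtype `B` a fully penetrant chr1p loss.  Repeated
#' calls return identical objects.
#'
#' @return A `SyntheticCohort` (see [simulate_cohort()]).
#' @export
fixture_small <- function() {
  design <- cohort_design(
    n_genes = 200,
    chromosomes = data.frame(chromosome = c("chr1", "chr2"),
                             p_length = 5e7, q_length = 6e7,
                             stringsAsFactors = FALSE),
    subtypes = list(
      list(label = "A", n_samples = 4, arm_events = list(),
           set_events = list(list(set = "PATHWAY_A", shift = 1.0))),
      list(label = "B", n_samples = 5,
           arm_events = list(list(chromosome = "chr1", arm = "p",
                                  shift = -0.8, penetrance = 1.0)),
           set_events = list()),
      list(label = "C", n_samples = 4, arm_events = list(),
           set_events = list())
    ),
    n_normals = 5, tissue = "kidney",
    d0_true = 4, s0sq_true = 0.09, mu0 = 8, sd0 = 1.5,
    n_marker_genes = 20, marker_shift = 1.2,
    planted_sets = list(
      list(name = "PATHWAY_A", size = 30),
      list(name = "PATHWAY_B", size = 20,
           overlap_with = "PATHWAY_A", n_overlap = 10)),
    n_random_sets = 5, random_set_size = 20,
    coupling = list(driver_gene = NULL, target_set = "PATHWAY_A",
                    rho_target = -0.6, activation_sd = 0.3,
                    driver_noise_sd = 0.3),
    replicates = list(sample = NULL, n_reps = 2),
    seed = 104729L)
  simulate_cohort(design)
}

#' Write all cohort files to a directory
#'
#' Emits exactly the plain-text formats the loaders read: `expression.tsv`,
#' `samples.tsv`, `annotation.tsv`, `cytoband.txt`, `sets.gmt`, plus the
#' design serialized as `design.yaml` for provenance.
#'
#' @param cohort A `SyntheticCohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  write_gene_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  cb <- cohort$cytoband
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", cb$chromosome,
                     format(cb$start, scientific = FALSE, trim = TRUE),
                     format(cb$end, scientific = FALSE, trim = TRUE),
                     cb$band, cb$stain),
             file.path(dir, "cytoband.txt"))
  write_gmt(cohort$sets, file.path(dir, "sets.gmt"))
  yaml::write_yaml(design_to_list(cohort$design), file.path(dir, "design.yaml"))
  invisible(dir)
}

design_to_list <- function(design) {
  d <- unclass(design)
  d$chromosomes <- as.list(as.data.frame(d$chromosomes))
  d
}
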