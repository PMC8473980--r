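## Synthetic dual-program breeding datasets: race-structured founder
## allele frequencies (Balding-Nichols), multigenerational pedigrees for
## two programs with a handful of shared founders, gene-dropped marker
## genotypes, field-trial phenotypes with regionally correlated breeding
## values, and controlled pedigree-error injection.  A truth log keeps
## everything needed for recovery tests.

# deterministic stage seeds derived from one master seed
stage_seed <- function(master, stage) {
  h <- 2166136261
  for (ch in utf8ToInt(stage)) h <- ((h * 16777619) %% 2147483647 + ch) %% 2147483647
  as.integer((master * 48271 + h) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: two breeding
#' programs founded on ~10 races/landraces with Balding-Nichols
#' population structure, a sparse candidate-gene marker panel, trials in
#' three regions with incomplete-block/row-plot designs, low growth
#' heritability with non-trivial dominance, and regionally correlated
#' additive effects.
#'
#' @param programs program labels.
#' @param regions region labels.
#' @param races race/landrace labels.
#' @param fst per-race differentiation from the ancestral pool
#'   (recycled).
#' @param landrace_mixtures optional named list: race label ->
#'   named weight vector over source races, defining landraces as
#'   admixtures.
#' @param n_markers marker panel size.
#' @param n_founders named count of base-population founders per
#'   program.
#' @param shared_founders founders common to both programs.
#' @param cryptic_pairs founder pairs given a hidden (unrecorded) common
#'   sire.
#' @param n_unpedigreed named count of genotyped selections per program
#'   with no pedigree or phenotype connection.
#' @param program_race_weights optional matrix (program x race) of
#'   founder race-sampling weights.
#' @param op_families,op_progeny open-pollinated (half-sib) families per
#'   program and progeny per family (generation 1).
#' @param generations total generations (1 = OP only; >=2 adds full-sib
#'   generations).
#' @param families_per_gen,progeny_per_family,parents_per_gen full-sib
#'   family structure per generation; `progeny_per_family` defaults to
#'   `plot_size * reps * trials_per_family` so every family fills one
#'   row-plot per replicate in each of its trials.
#' @param trials data frame (program, region, n_trials) giving the trial
#'   network.
#' @param trials_per_family number of trials each family is planted in.
#' @param reps,iblocks_per_rep,plot_size replications, incomplete blocks
#'   per replicate, and trees per contiguous family row-plot.
#' @param checklots_per_trial,checklot_trees unpedigreed commercial
#'   checklot entries per trial and trees across them.
#' @param traits named list of per-trait variance settings
#'   (`sigma2_a`, `r_a`, `sigma2_f`, `sigma2_b`, `sigma2_p`,
#'   `sigma2_e`); defaults give h2 ~0.15 / d2 ~0.12 for VOL and moderate
#'   h2 for the wood traits.
#' @param sigma2_race variance of race mean shifts in breeding value.
#' @param wood_trial_fraction,wood_tree_fraction share of trials and of
#'   trees within them assessed for the wood traits.
#' @param trial_mean,trial_mean_sd trial mean level and spread.
#' @param checklot_sd spread of fixed checklot means.
#' @param genotyped_parent_fraction fraction of progeny-tested parents
#'   that are genotyped.
#' @param genotyped_nonparents genotyped non-parent progeny per program.
#' @param missing_rate genotype missing-call rate.
#' @param pedigree_error_rate fraction of non-founders given a wrong
#'   recorded sire.
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    programs = c("EG1", "EG2"),
    regions = c("WA", "GT", "GIPPS"),
    races = c("STRZ", "FURNX", "NE_TAS", "SE_TAS", "W_TAS",
              "KI", "W_OTW", "E_OTW", "PORT", "CALIF"),
    fst = 0.1,
    landrace_mixtures = NULL,
    n_markers = 2500,
    n_founders = c(EG1 = 112, EG2 = 83),
    shared_founders = 4,
    cryptic_pairs = 0,
    n_unpedigreed = c(EG1 = 20, EG2 = 5),
    program_race_weights = NULL,
    op_families = 20, op_progeny = 16,
    generations = 3,
    families_per_gen = 30, progeny_per_family = NULL, parents_per_gen = 60,
    trials = NULL,
    trials_per_family = 2,
    reps = 4, iblocks_per_rep = 4, plot_size = 4,
    checklots_per_trial = 3, checklot_trees = 40,
    traits = NULL,
    sigma2_race = 0.4,
    wood_trial_fraction = 0.4, wood_tree_fraction = 0.3,
    trial_mean = 100, trial_mean_sd = 10,
    checklot_sd = 1,
    genotyped_parent_fraction = 0.8,
    genotyped_nonparents = 20,
    missing_rate = 0.02,
    pedigree_error_rate = 0) {
  if (is.null(trials))
    trials <- data.frame(
      program = c("EG1", "EG1", "EG2", "EG2", "EG2"),
      region = c("WA", "GT", "WA", "GT", "GIPPS"),
      n_trials = c(3, 1, 1, 2, 2),
      stringsAsFactors = FALSE)
  trials <- trials[trials$program %in% programs, , drop = FALSE]
  if (is.null(traits))
    traits <- list(
      VOL = list(sigma2_a = 1, r_a = 0.7, sigma2_f = 0.2,
                 sigma2_b = 0.3, sigma2_p = 0.3, sigma2_e = 4.87),
      DENS = list(sigma2_a = 1, r_a = 0.9, sigma2_f = 0.07,
                  sigma2_b = 0.2, sigma2_p = 0.2, sigma2_e = 1.39),
      CELL = list(sigma2_a = 1, r_a = 0.9, sigma2_f = 0.08,
                  sigma2_b = 0.2, sigma2_p = 0.2, sigma2_e = 1.85))
  if (is.null(program_race_weights)) {
    program_race_weights <- matrix(1, length(programs), length(races),
                                   dimnames = list(programs, races))
    # EG1 influenced by Furneaux, King Island, Portugal, NE Tasmania;
    # EG2 founded half on Strzelecki and Western Otways
    if (all(c("EG1", "EG2") %in% programs) &&
        all(c("FURNX", "KI", "PORT", "NE_TAS", "STRZ", "W_OTW") %in% races)) {
      program_race_weights["EG1", c("FURNX", "KI", "PORT", "NE_TAS")] <- 4
      program_race_weights["EG2", c("STRZ", "W_OTW")] <- 6
    }
  }
  fst <- stats::setNames(rep_len(fst, length(races)), races)
  # full-sib families fill plot_size-tree row-plots in every replicate of
  # each trial they are planted in (the standard progeny-trial layout)
  if (is.null(progeny_per_family))
    progeny_per_family <- plot_size * reps * trials_per_family
  cfg <- mget(setdiff(names(formals(sim_config)), ""),
              envir = environment())
  structure(cfg, class = "sim_config")
}

#' Race-structured founder allele frequencies
#'
#' Ancestral frequencies are drawn Uniform(0.1, 0.9); each race's
#' frequency at marker j follows the Balding-Nichols model
#' `Beta(p (1-Fst)/Fst, (1-p)(1-Fst)/Fst)`, so the variance of race
#' frequencies around the ancestral value is `p (1-p) Fst`.  Landraces
#' declared as mixtures take weighted averages of their source races'
#' frequencies.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `ancestral` (length-m vector) and `race_freq`
#'   (m x races matrix).
#' @export
simulate_founder_alleles <- function(cfg, seed = 1L) {
  set.seed(stage_seed(seed, "founder_alleles"))
  m <- cfg$n_markers
  p <- stats::runif(m, 0.1, 0.9)
  rf <- matrix(NA_real_, m, length(cfg$races),
               dimnames = list(NULL, cfg$races))
  for (r in cfg$races) {
    f <- cfg$fst[[r]]
    rf[, r] <- if (f <= 0) p else
      stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  for (lr in names(cfg$landrace_mixtures)) {
    w <- cfg$landrace_mixtures[[lr]]
    w <- w / sum(w)
    rf[, lr] <- rf[, names(w), drop = FALSE] %*% w
  }
  list(ancestral = p, race_freq = rf)
}

# allocate founder races for a program by its race weights
sample_races <- function(cfg, program, n) {
  w <- cfg$program_race_weights[program, ]
  sample(cfg$races, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate the pedigrees of two breeding programs
#'
#' Builds, per program, a founder base, open-pollinated (half-sib)
#' families in generation 1, and full-sib factorial matings in later
#' generations with parents selected from the previous generation.  A
#' configurable number of founders is shared between programs (single
#' pedigree nodes), and `cryptic_pairs` same-race founder pairs are
#' given a hidden common sire present only in the gene-drop pedigree.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return List with `pedigree` (recorded), `drop_pedigree` (true
#'   genetic pedigree incl. hidden ancestors), `families` (data frame),
#'   and id bookkeeping (`founders`, `unpedigreed`, `shared`).
#' @export
simulate_breeding_programs <- function(cfg, seed = 1L) {
  set.seed(stage_seed(seed, "breeding_programs"))
  rec <- list(); fam <- list(); founders <- list(); unped <- list()
  shared <- character(0)
  hidden <- list()
  progeny_of <- list()
  first_prog <- cfg$programs[1L]
  for (pi in seq_along(cfg$programs)) {
    pr <- cfg$programs[pi]
    nf <- cfg$n_founders[[pr]]
    n_sh <- if (pi > 1L) min(cfg$shared_founders, length(founders[[first_prog]])) else 0L
    own <- nf - n_sh
    fid <- sprintf("%s:F%03d", pr, seq_len(own))
    frace <- sample_races(cfg, pr, own)
    rec[[length(rec) + 1L]] <- data.frame(
      id = fid, sire = NA_character_, dam = NA_character_,
      race = frace, program = pr, stringsAsFactors = FALSE)
    founders[[pr]] <- c(if (n_sh) founders[[first_prog]][seq_len(n_sh)],
                        fid)
    if (pi > 1L && n_sh)
      shared <- founders[[first_prog]][seq_len(n_sh)]
    nu <- cfg$n_unpedigreed[[pr]]
    if (!is.null(nu) && nu > 0) {
      uid <- sprintf("%s:U%03d", pr, seq_len(nu))
      rec[[length(rec) + 1L]] <- data.frame(
        id = uid, sire = NA_character_, dam = NA_character_,
        race = sample_races(cfg, pr, nu), program = pr,
        stringsAsFactors = FALSE)
      unped[[pr]] <- uid
    }
  }
  # cryptic founder relatedness: hidden common sire per pair
  all_f <- do.call(rbind, rec)
  all_f <- all_f[!all_f$id %in% unlist(unped), , drop = FALSE]
  if (cfg$cryptic_pairs > 0) {
    by_race <- split(all_f$id, all_f$race)
    by_race <- by_race[vapply(by_race, length, 1L) >= 2]
    take <- sample(names(by_race),
                   min(cfg$cryptic_pairs, length(by_race)))
    for (k in seq_along(take)) {
      pair <- sample(by_race[[take[k]]], 2)
      hid <- sprintf("HIDDEN:H%03d", k)
      hidden[[k]] <- list(id = hid, race = take[k], pair = pair)
    }
  }
  next_gen_parents <- founders
  counter <- 0L
  for (gen in seq_len(cfg$generations)) {
    for (pr in cfg$programs) {
      if (gen == 1L) {
        if (cfg$op_families <= 0) next
        dams <- sample(founders[[pr]],
                       min(cfg$op_families, length(founders[[pr]])))
        for (dm in dams) {
          counter <- counter + 1L
          fid <- sprintf("%s:OPF%04d", pr, counter)
          kid <- sprintf("%s:G1_%05d", pr,
                         seq_len(cfg$op_progeny) + counter * 1000L)
          rec[[length(rec) + 1L]] <- data.frame(
            id = kid, sire = NA_character_, dam = dm,
            race = NA_character_, program = pr, stringsAsFactors = FALSE)
          fam[[length(fam) + 1L]] <- data.frame(
            family = fid, program = pr, generation = gen,
            sire = NA_character_, dam = dm, type = "half-sib",
            n = cfg$op_progeny, stringsAsFactors = FALSE)
          progeny_of[[fid]] <- kid
        }
      } else {
        pool <- next_gen_parents[[pr]]
        # mate a limited parent set so each parent appears in several
        # families (factorial-style reuse, as in operational programs;
        # this is also what identifies additive against family variance)
        if (length(pool) > cfg$parents_per_gen)
          pool <- sample(pool, cfg$parents_per_gen)
        n_fam <- cfg$families_per_gen
        max_pairs <- choose(length(pool), 2)
        if (n_fam > max_pairs)
          stop("requested families exceed possible parent pairs (",
               n_fam, " > ", max_pairs, ")")
        pairs <- unique(t(replicate(n_fam * 4, sort(sample(pool, 2)))))
        pairs <- pairs[seq_len(min(n_fam, nrow(pairs))), , drop = FALSE]
        kids_all <- character(0)
        for (k in seq_len(nrow(pairs))) {
          counter <- counter + 1L
          fid <- sprintf("%s:CPF%04d", pr, counter)
          kid <- sprintf("%s:G%d_%05d", pr, gen,
                         seq_len(cfg$progeny_per_family) + counter * 1000L)
          rec[[length(rec) + 1L]] <- data.frame(
            id = kid, sire = pairs[k, 1L], dam = pairs[k, 2L],
            race = NA_character_, program = pr, stringsAsFactors = FALSE)
          fam[[length(fam) + 1L]] <- data.frame(
            family = fid, program = pr, generation = gen,
            sire = pairs[k, 1L], dam = pairs[k, 2L], type = "full-sib",
            n = cfg$progeny_per_family, stringsAsFactors = FALSE)
          progeny_of[[fid]] <- kid
          kids_all <- c(kids_all, kid)
        }
        next_gen_parents[[pr]] <-
          sample(kids_all, min(cfg$parents_per_gen, length(kids_all)))
      }
    }
  }
  recdf <- do.call(rbind, rec)
  ped <- pedigree(recdf$id, recdf$sire, recdf$dam, recdf$race,
                  recdf$program)
  dropdf <- recdf
  if (length(hidden)) {
    hdf <- do.call(rbind, lapply(hidden, function(h)
      data.frame(id = h$id, sire = NA_character_, dam = NA_character_,
                 race = h$race, program = "HIDDEN",
                 stringsAsFactors = FALSE)))
    for (h in hidden)
      dropdf$sire[dropdf$id %in% h$pair] <- h$id
    dropdf <- rbind(hdf, dropdf)
  }
  drop_ped <- pedigree(dropdf$id, dropdf$sire, dropdf$dam, dropdf$race,
                       dropdf$program)
  list(pedigree = ped, drop_pedigree = drop_ped,
       families = do.call(rbind, fam), progeny_of = progeny_of,
       founders = founders, unpedigreed = unped, shared = shared,
       hidden = hidden)
}

#' Gene-drop marker genotypes down a pedigree
#'
#' Founders draw both alleles Binomial(1, p_race) at each marker; every
#' offspring allele is drawn uniformly from the corresponding parent's
#' two alleles, independently per marker (no linkage).  An unknown
#' parent contributes alleles drawn from the individual's expected race
#' mixture (via the group-fraction matrix).
#'
#' @param p a sorted [pedigree()] (the true genetic pedigree).
#' @param race_freq m x races matrix of race allele frequencies (from
#'   [simulate_founder_alleles()]); optional when `founder_scores` is
#'   given.
#' @param founder_scores optional [marker_matrix()] of founder 0/1/2
#'   scores (heterozygote phase randomized) overriding the frequency
#'   draws for those founders.
#' @param ids optional subset of ids to return.
#' @param seed integer seed.
#' @return A [marker_matrix()] of 0/1/2 scores (no missingness).
#' @export
gene_drop <- function(p, race_freq = NULL, founder_scores = NULL,
                      ids = NULL, seed = 1L) {
  set.seed(stage_seed(seed, "gene_drop"))
  p <- ensure_sorted(p)
  n <- nrow(p)
  m <- if (!is.null(race_freq)) nrow(race_freq) else
    length(founder_scores$markers)
  idx <- match_parents(p)
  Q <- group_fraction_matrix(p)
  qmat <- Q$values
  freq_cols <- if (!is.null(race_freq)) {
    cols <- matrix(0.5, m, length(Q$groups),
                   dimnames = list(NULL, Q$groups))
    known <- intersect(Q$groups, colnames(race_freq))
    cols[, known] <- race_freq[, known]
    cols
  } else matrix(0.5, m, length(Q$groups),
                dimnames = list(NULL, Q$groups))
  mix_freq <- function(i) as.numeric(freq_cols %*% qmat[i, ])
  A1 <- matrix(0L, n, m); A2 <- matrix(0L, n, m)
  fs_idx <- if (!is.null(founder_scores))
    match(p$id, founder_scores$ids) else rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- idx$sire[i]; d <- idx$dam[i]
    if (s == 0L && d == 0L) {
      if (!is.na(fs_idx[i])) {
        sc <- founder_scores$scores[fs_idx[i], ]
        a1 <- as.integer(sc >= 1); a2 <- as.integer(sc == 2)
        het <- sc == 1
        swap <- stats::runif(sum(het)) < 0.5
        a1h <- a1[het]; a2h <- a2[het]
        a1[het][swap] <- a2h[swap]; a2[het][swap] <- a1h[swap]
        A1[i, ] <- a1; A2[i, ] <- a2
      } else {
        pf <- mix_freq(i)
        A1[i, ] <- stats::rbinom(m, 1L, pf)
        A2[i, ] <- stats::rbinom(m, 1L, pf)
      }
      next
    }
    take <- function(j) {
      if (j == 0L) return(stats::rbinom(m, 1L, mix_freq(i)))
      pick <- stats::runif(m) < 0.5
      ifelse(pick, A1[j, ], A2[j, ])
    }
    A1[i, ] <- take(s)
    A2[i, ] <- take(d)
  }
  scores <- A1 + A2
  rownames(scores) <- p$id
  colnames(scores) <- if (!is.null(founder_scores))
    founder_scores$markers else sprintf("M%05d", seq_len(m))
  keep <- if (is.null(ids)) p$id else ids
  marker_matrix(scores[keep, , drop = FALSE], ids = keep,
                markers = colnames(scores))
}

#' Simulate field-trial phenotypes with a truth log
#'
#' True breeding values are polygenic and regionally correlated:
#' founders draw from `MVN(race shift, Sigma_a)` and offspring from the
#' parent mean plus a Mendelian deviation with covariance
#' `0.5 (1 - (F_s + F_d)/2) Sigma_a`; an unknown parent is replaced by
#' an independent founder-like draw from the known parent's race
#' profile.  Records receive family (SCA), incomplete-block, row-plot
#' and residual effects on top of the trial mean; checklot entries get
#' fixed checklot means and no pedigree link.
#'
#' @param sim output of [simulate_breeding_programs()].
#' @param cfg the [sim_config()].
#' @param seed integer seed.
#' @return List with `phenotypes` (data frame) and `truth` (true
#'   breeding values per trait, family and design effects, race
#'   shifts).
#' @export
simulate_phenotypes <- function(sim, cfg, seed = 1L) {
  set.seed(stage_seed(seed, "phenotypes"))
  ped <- ensure_sorted(sim$drop_pedigree)
  n <- nrow(ped)
  idx <- match_parents(ped)
  F <- inbreeding_meuwissen_luo(ped)
  Q <- group_fraction_matrix(ped)
  R <- length(cfg$regions)
  corrmat <- function(r_a) {
    C <- matrix(r_a, R, R); diag(C) <- 1; C
  }
  race_shift <- list(); bv <- list()
  for (tr in names(cfg$traits)) {
    tc <- cfg$traits[[tr]]
    Sigma <- tc$sigma2_a * corrmat(tc$r_a)
    Lfull <- t(chol(Sigma))
    shifts <- stats::setNames(stats::rnorm(length(Q$groups), 0,
                                           sqrt(cfg$sigma2_race)),
                              Q$groups)
    shifts["UNKNOWN_RACE"] <- 0   # no shift for the unknown-parent group
    shifts <- shifts[Q$groups]; shifts[is.na(shifts)] <- 0
    B <- matrix(0, n, R, dimnames = list(ped$id, cfg$regions))
    base_shift <- as.numeric(Q$values %*% shifts)
    for (i in seq_len(n)) {
      s <- idx$sire[i]; d <- idx$dam[i]
      if (s == 0L && d == 0L) {
        B[i, ] <- base_shift[i] + as.numeric(Lfull %*% stats::rnorm(R))
      } else {
        bs <- if (s != 0L) B[s, ] else
          2 * base_shift[i] - (if (d != 0L) base_shift[d] else 0) +
          as.numeric(Lfull %*% stats::rnorm(R))
        bd <- if (d != 0L) B[d, ] else
          2 * base_shift[i] - (if (s != 0L) base_shift[s] else 0) +
          as.numeric(Lfull %*% stats::rnorm(R))
        Fs <- if (s != 0L) F[s] else 0
        Fd <- if (d != 0L) F[d] else 0
        Lm <- Lfull * sqrt(0.5 * (1 - (Fs + Fd) / 2))
        B[i, ] <- 0.5 * (bs + bd) + as.numeric(Lm %*% stats::rnorm(R))
      }
    }
    bv[[tr]] <- B
    race_shift[[tr]] <- shifts
  }
  # trial network
  trials <- do.call(rbind, lapply(seq_len(nrow(cfg$trials)), function(k) {
    tr <- cfg$trials[k, ]
    data.frame(trial = sprintf("%s_%s_T%d", tr$program, tr$region,
                               seq_len(tr$n_trials)),
               program = tr$program, region = tr$region,
               stringsAsFactors = FALSE)
  }))
  trials$mean <- stats::rnorm(nrow(trials), cfg$trial_mean,
                              cfg$trial_mean_sd)
  wood_trials <- unlist(lapply(split(trials$trial, trials$program),
                               function(tt) tt[seq_len(max(1, round(
                                 length(tt) * cfg$wood_trial_fraction)))]))
  # assign family progeny to trials: each family fills plot_size-tree
  # row-plots across the replicates of each of its trials
  recs <- list()
  famtab <- sim$families
  if (is.null(famtab)) famtab <- data.frame()
  for (k in seq_len(nrow(famtab))) {
    fm <- famtab[k, ]
    ptr <- trials[trials$program == fm$program, , drop = FALSE]
    ntr <- min(cfg$trials_per_family, nrow(ptr))
    tsel <- ptr[sample(nrow(ptr), ntr), , drop = FALSE]
    kids <- sim$progeny_of[[fm$family]]
    per_trial <- cfg$plot_size * cfg$reps
    used <- 0L
    part <- list()
    for (t in seq_len(ntr)) {
      take <- min(per_trial, length(kids) - used)
      if (take <= 0L) break
      kk <- kids[used + seq_len(take)]
      used <- used + take
      rep_asn <- rep(seq_len(cfg$reps), each = cfg$plot_size)[seq_len(take)]
      part[[t]] <- data.frame(
        tree_id = kk, program = fm$program, trial = tsel$trial[t],
        region = tsel$region[t], family = fm$family,
        entry_type = fm$type, checklot_id = NA_character_,
        replicate = rep_asn,
        plot = paste0(fm$family, ".R", rep_asn),
        stringsAsFactors = FALSE)
    }
    recs[[k]] <- do.call(rbind, part)
  }
  # checklot entries per trial
  ckrecs <- lapply(seq_len(nrow(trials)), function(k) {
    tr <- trials[k, ]
    nck <- cfg$checklots_per_trial
    if (nck <= 0 || cfg$checklot_trees <= 0) return(NULL)
    cks <- sprintf("%s:CK%02d", tr$program, seq_len(nck))
    ntree <- cfg$checklot_trees
    data.frame(
      tree_id = sprintf("%s:CKT_%03d", tr$trial, seq_len(ntree)),
      program = tr$program, trial = tr$trial, region = tr$region,
      family = paste0("CK.", rep_len(cks, ntree)),
      entry_type = "checklot",
      checklot_id = rep_len(cks, ntree), stringsAsFactors = FALSE)
  })
  ckdf <- do.call(rbind, ckrecs)
  if (!is.null(ckdf) && nrow(ckdf)) {
    # checklot trees fill plots the same way, cycling over replicates
    ckdf$replicate <- NA_integer_; ckdf$plot <- NA_character_
    for (key in unique(paste(ckdf$trial, ckdf$family))) {
      fr <- which(paste(ckdf$trial, ckdf$family) == key)
      rp <- rep(seq_len(cfg$reps),
                each = cfg$plot_size)[seq_along(fr) %% (cfg$plot_size * cfg$reps) + 1L]
      ckdf$replicate[fr] <- rp
      ckdf$plot[fr] <- paste0(ckdf$family[fr], ".R", rp)
    }
  }
  ph <- rbind(do.call(rbind, recs), ckdf)
  # incomplete blocks: plots within each replicate allocated at random
  ph$iblock <- NA_integer_
  for (tl in unique(ph$trial)) {
    rows <- which(ph$trial == tl)
    for (rp in unique(ph$replicate[rows])) {
      rr <- rows[ph$replicate[rows] == rp]
      plots <- unique(ph$plot[rr])
      ib <- sample(rep_len(seq_len(cfg$iblocks_per_rep), length(plots)))
      ph$iblock[rr] <- ib[match(ph$plot[rr], plots)]
    }
  }
  # effects and trait values
  truth_fx <- list()
  for (tr in names(cfg$traits)) {
    tc <- cfg$traits[[tr]]
    famkey <- unique(ph$family[ph$entry_type != "checklot"])
    fameff <- matrix(stats::rnorm(length(famkey) * R, 0, sqrt(tc$sigma2_f)),
                     length(famkey), R,
                     dimnames = list(famkey, cfg$regions))
    ckkey <- unique(stats::na.omit(ph$checklot_id))
    ckeff <- stats::setNames(stats::rnorm(length(ckkey), 0,
                                          cfg$checklot_sd), ckkey)
    bkey <- unique(paste(ph$trial, ph$replicate, ph$iblock, sep = ":"))
    beff <- stats::setNames(stats::rnorm(length(bkey), 0,
                                         sqrt(tc$sigma2_b)), bkey)
    pkey <- unique(paste(ph$trial, ph$replicate, ph$plot, sep = ":"))
    peff <- stats::setNames(stats::rnorm(length(pkey), 0,
                                         sqrt(tc$sigma2_p)), pkey)
    tmean <- stats::setNames(trials$mean, trials$trial)
    g <- numeric(nrow(ph))
    pedrow <- match(ph$tree_id, ped$id)
    has_ped <- !is.na(pedrow)
    g[has_ped] <- bv[[tr]][cbind(pedrow[has_ped],
                                 match(ph$region, cfg$regions)[has_ped])]
    famv <- fameff[cbind(match(ph$family, famkey),
                         match(ph$region, cfg$regions))]
    famv[is.na(famv)] <- 0
    ckv <- ifelse(is.na(ph$checklot_id), 0, ckeff[ph$checklot_id])
    y <- tmean[ph$trial] + g + famv + ckv +
      beff[paste(ph$trial, ph$replicate, ph$iblock, sep = ":")] +
      peff[paste(ph$trial, ph$replicate, ph$plot, sep = ":")] +
      stats::rnorm(nrow(ph), 0, sqrt(tc$sigma2_e))
    if (tr != "VOL") {
      y[!(ph$trial %in% wood_trials)] <- NA
      meas <- !is.na(y)
      drop <- meas & stats::runif(nrow(ph)) > cfg$wood_tree_fraction
      y[drop] <- NA
    }
    ph[[tr]] <- as.numeric(y)
    truth_fx[[tr]] <- list(family = fameff, checklot = ckeff,
                           iblock = beff, plot = peff)
  }
  rownames(ph) <- NULL
  list(phenotypes = ph,
       truth = list(bv = bv, effects = truth_fx,
                    race_shift = race_shift, trials = trials,
                    inbreeding = F))
}

#' Inject pedigree errors
#'
#' Replaces the recorded sire of a random fraction of non-founders with
#' a random earlier-generation individual of the same program (so the
#' pedigree stays acyclic), logging every swap.
#'
#' @param p a sorted [pedigree()].
#' @param rate fraction in \[0, 1) of eligible non-founders corrupted.
#' @param seed integer seed.
#' @return List with `pedigree` (corrupted) and `errors` (data frame:
#'   id, true_sire, false_sire).
#' @export
inject_pedigree_errors <- function(p, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(stage_seed(seed, "pedigree_errors"))
  p <- ensure_sorted(p)
  if (rate == 0)
    return(list(pedigree = p,
                errors = data.frame(id = character(0),
                                    true_sire = character(0),
                                    false_sire = character(0))))
  elig <- which(!is.na(p$sire))
  hit <- elig[stats::runif(length(elig)) < rate]
  errors <- list()
  idx <- match_parents(p)
  # recorded ancestors up to grandparents, for the unrelatedness screen
  anc2 <- function(i) {
    par <- c(idx$sire[i], idx$dam[i]); par <- par[par != 0L]
    gp <- c(idx$sire[par], idx$dam[par]); gp <- gp[gp != 0L]
    unique(c(i, par, gp))
  }
  for (i in hit) {
    fam_i <- anc2(i)
    cand <- which(seq_len(nrow(p)) < i & p$program == p$program[i])
    # a false sire is an unrelated contemporary: screen out the
    # individual's own recorded family (shared parents/grandparents)
    cand <- cand[vapply(cand, function(c)
      length(intersect(anc2(c), fam_i)) == 0L, TRUE)]
    if (!length(cand)) next
    new_sire <- p$id[cand[sample.int(length(cand), 1L)]]
    errors[[length(errors) + 1L]] <- data.frame(
      id = p$id[i], true_sire = p$sire[i], false_sire = new_sire,
      stringsAsFactors = FALSE)
    p$sire[i] <- new_sire
  }
  list(pedigree = topo_sort_validate(p),
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(id = character(0), true_sire = character(0),
                    false_sire = character(0)))
}

#' Generate a complete synthetic dual-program dataset
#'
#' End-to-end driver: founder allele frequencies, program pedigrees,
#' gene-dropped genotypes for the genotyped subset (progeny-tested
#' parents, unpedigreed selections and some non-parent progeny),
#' field-trial phenotypes, and optional pedigree-error injection.  All
#' randomness derives from the master seed through stable per-stage
#' seeds, so identical configurations reproduce identical datasets.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return List with `pedigree` (recorded, possibly corrupted),
#'   `true_pedigree`, `drop_pedigree`, `genotypes` ([marker_matrix()]
#'   with missing calls), `genotyped`, `phenotypes`, `truth` (truth log
#'   incl. injected errors) and `config`.
#' @export
simulate_breeding_data <- function(cfg = sim_config(), seed = 1L) {
  al <- simulate_founder_alleles(cfg, seed)
  sim <- simulate_breeding_programs(cfg, seed)
  phe <- simulate_phenotypes(sim, cfg, seed)
  ped <- sim$pedigree
  # genotyped subset: progeny-tested parents + unpedigreed selections +
  # some non-parent progeny
  set.seed(stage_seed(seed, "genotyped_subset"))
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  gp <- parents[stats::runif(length(parents)) <
                  cfg$genotyped_parent_fraction]
  nonpar <- setdiff(ped$id[!is_founder(ped)],
                    c(parents, unique(phe$phenotypes$tree_id[
                      phe$phenotypes$entry_type == "half-sib"])))
  extra <- unlist(lapply(cfg$programs, function(pr) {
    pool <- nonpar[startsWith(nonpar, paste0(pr, ":"))]
    sample(pool, min(cfg$genotyped_nonparents, length(pool)))
  }))
  genotyped <- unique(c(gp, unlist(sim$unpedigreed), extra))
  mm <- gene_drop(sim$drop_pedigree, al$race_freq, ids = genotyped,
                  seed = seed)
  set.seed(stage_seed(seed, "missingness"))
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(mm$scores)) < cfg$missing_rate,
                   nrow(mm$scores))
    mm$scores[mask] <- NA
  }
  err <- inject_pedigree_errors(ped, cfg$pedigree_error_rate, seed)
  truth <- phe$truth
  truth$errors <- err$errors
  truth$race_freq <- al$race_freq
  list(pedigree = err$pedigree, true_pedigree = ped,
       drop_pedigree = sim$drop_pedigree, genotypes = mm,
       genotyped = genotyped, phenotypes = phe$phenotypes,
       truth = truth, families = sim$families,
       unpedigreed = sim$unpedigreed, shared = sim$shared,
       config = cfg, seed = seed)
}

#' Write a simulated dataset in the file dialects read by the package
#'
#' Emits `pedigree.csv` (id, sire, dam, race, program),
#' `genotypes.tsv`, `phenotypes.csv`, `truth.json` and `config.yaml`.
#'
#' @param sim output of [simulate_breeding_data()].
#' @param dir output directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(sim$pedigree)
  ped$sire[is.na(ped$sire)] <- "0"; ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE)
  gt <- data.frame(id = sim$genotypes$ids,
                   as.data.frame(sim$genotypes$scores),
                   check.names = FALSE)
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    bv = lapply(sim$truth$bv, function(B)
      data.frame(id = rownames(B), as.data.frame(B))),
    race_shift = sim$truth$race_shift,
    errors = sim$truth$errors)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  cfg <- sim$config
  cfg$traits <- lapply(cfg$traits, unlist)
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file of [sim_config()] fields.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(sim_config)))
  vals <- vals[keep]
  if (!is.null(vals$trials)) vals$trials <- as.data.frame(vals$trials)
  if (!is.null(vals$n_founders)) vals$n_founders <- unlist(vals$n_founders)
  if (!is.null(vals$n_unpedigreed))
    vals$n_unpedigreed <- unlist(vals$n_unpedigreed)
  if (!is.null(vals$traits)) vals$traits <- lapply(vals$traits, as.list)
  do.call(sim_config, vals)
}
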