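#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' design the package targets: two groups of 8 and 9 bulk samples, 43
#' reference cell types with a few markers each, a pool of low-expression
#' background transcripts to exercise the expression filter, and negative
#' binomial count noise with gene-level overdispersion.
#'
#' @param n_cell_types Number of reference cell types (default 43).
#' @param markers_per_type Unique marker genes per cell type (default 3).
#' @param n_shared_markers Genes deliberately listed under two cell types, to
#'   exercise duplicate removal in [build_reference()] (default 10).
#' @param n_background_genes Non-marker genes in the bulk matrix
#'   (default 2000; the study-scale pool of ~27,000 is defaulted down).
#' @param group_sizes Samples per group (default `c(8, 9)`).
#' @param group_labels Group labels (default `c("F", "M")`).
#' @param proportions Either a single Dirichlet concentration (default 1;
#'   one weight vector is drawn and shared by both groups, i.e. no true
#'   composition difference) or a numeric matrix of explicit mixture weights
#'   (cell types x 2 groups, columns summing to 1; zero rows mark absent
#'   cell types).
#' @param library_size_mean,library_size_cv Nominal library size scale and
#'   its between-sample coefficient of variation (defaults 1e6, 0.2).
#' @param nb_dispersion Negative binomial dispersion (default 0.1, standard
#'   bulk RNA-Seq overdispersion).
#' @param n_group_diff_genes,effect_size Marker genes given a true group
#'   difference of `effect_size` log2 fold change in the second group
#'   (defaults 0, 1).
#' @param n_exclusive_genes Length-2 integer vector: marker genes made
#'   structurally zero in the *other* group, per group (default `c(0, 0)`).
#' @param isoform_fraction Fraction of marker genes emitted as two transcript
#'   isoforms of one symbol (default 0.25).
#' @param qc_group_means Optional named list of length-2 numeric vectors
#'   overriding per-group means of the QC metrics.
#' @param seed Integer seed fixing all generator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 43,
                       markers_per_type = 3,
                       n_shared_markers = 10,
                       n_background_genes = 2000,
                       group_sizes = c(8, 9),
                       group_labels = c("F", "M"),
                       proportions = 1,
                       library_size_mean = 1e6,
                       library_size_cv = 0.2,
                       nb_dispersion = 0.1,
                       n_group_diff_genes = 0,
                       effect_size = 1,
                       n_exclusive_genes = c(0, 0),
                       isoform_fraction = 0.25,
                       qc_group_means = NULL,
                       seed = 1) {
  stopifnot(n_cell_types >= 1, markers_per_type >= 1, n_shared_markers >= 0,
            n_background_genes >= 0, length(group_sizes) == 2,
            all(group_sizes >= 2), length(group_labels) == 2,
            library_size_mean > 0, nb_dispersion > 0,
            n_group_diff_genes >= 0, length(n_exclusive_genes) == 2,
            isoform_fraction >= 0, isoform_fraction <= 1)
  if (is.matrix(proportions)) {
    stopifnot(nrow(proportions) == n_cell_types, ncol(proportions) == 2,
              all(proportions >= 0),
              all(abs(colSums(proportions) - 1) < 1e-9))
  } else {
    stopifnot(length(proportions) == 1, proportions > 0)
  }
  structure(list(
    n_cell_types = n_cell_types, markers_per_type = markers_per_type,
    n_shared_markers = n_shared_markers,
    n_background_genes = n_background_genes,
    group_sizes = group_sizes, group_labels = group_labels,
    proportions = proportions, library_size_mean = library_size_mean,
    library_size_cv = library_size_cv, nb_dispersion = nb_dispersion,
    n_group_diff_genes = n_group_diff_genes, effect_size = effect_size,
    n_exclusive_genes = n_exclusive_genes,
    isoform_fraction = isoform_fraction,
    qc_group_means = qc_group_means, seed = as.integer(seed)),
    class = "sim_config")
}

cell_type_names <- function(n) sprintf("cell_type_%02d", seq_len(n))

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate per-cell-type marker tables
#'
#' Writes one CSV per cell type (columns `gene_symbol`, `expression`,
#' `cell_type`) containing the cell type's unique markers plus the configured
#' number of shared genes duplicated into a second cell type. The returned
#' ground truth lists exactly the genes a correct [build_reference()] must
#' retain.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); files go to
#'   `dir/markers/`.
#' @return A list with `files` (paths written) and `truth`
#'   (`unique_marker_map` tibble plus `shared_genes`).
#' @export
simulate_markers <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$markers_per_type == 0) abort("markers_per_type must be >= 1.")
  mdir <- file.path(dir, "markers")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  types <- cell_type_names(cfg$n_cell_types)
  with_sim_seed(cfg$seed, {
    unique_map <- tibble(
      gene_symbol = sprintf("MK%02d_%d",
                            rep(seq_len(cfg$n_cell_types),
                                each = cfg$markers_per_type),
                            rep(seq_len(cfg$markers_per_type),
                                cfg$n_cell_types)),
      cell_type = rep(types, each = cfg$markers_per_type),
      expression = round(rlnorm(cfg$n_cell_types * cfg$markers_per_type,
                                log(50), 1), 3))
    shared <- if (cfg$n_shared_markers > 0 && cfg$n_cell_types >= 2) {
      map_dfr(seq_len(cfg$n_shared_markers), function(i) {
        cts <- sample(types, 2)
        tibble(gene_symbol = sprintf("SH%02d", i), cell_type = cts,
               expression = round(rlnorm(2, log(50), 1), 3))
      })
    } else {
      tibble(gene_symbol = character(), cell_type = character(),
             expression = double())
    }
    all_rows <- bind_rows(unique_map, shared)
    files <- map_chr(types, function(ct) {
      path <- file.path(mdir, paste0(ct, ".csv"))
      rows <- all_rows |>
        filter(.data$cell_type == ct) |>
        select("gene_symbol", "expression", "cell_type") |>
        arrange(.data$gene_symbol)
      write_delim_plain(rows, path)
      path
    })
    list(files = files,
         truth = list(
           unique_marker_map = select(unique_map, "gene_symbol",
                                      "cell_type"),
           shared_genes = unique(shared$gene_symbol)))
  })
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a bulk count matrix with known ground truth
#'
#' Generates raw negative binomial counts for a two-group bulk RNA-Seq
#' design. The expected count of marker gene `g` of cell type `c` in sample
#' `s` is `library_size(s) * weight(c, group(s)) * intensity(g)`; group
#' differences are planted as a log2 fold change in the second group,
#' group-exclusive genes as structural zeros in the other group. A fraction
#' of marker genes is emitted as two transcript isoforms of one symbol, and
#' background genes are drawn at low expectation (some below a mean of 1) to
#' exercise the expression filter.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground-truth fragment from [simulate_markers()] (its
#'   `$truth` element or the full return value).
#' @param dir Output directory; writes `counts.csv` and `groups.csv`.
#' @return A list with `counts_path`, `groups_path`, and `truth` extended
#'   with `weights`, `present_cell_types`, `group_diff_genes`,
#'   `exclusive_genes`, `n_transcripts`, and per-transcript expectations.
#' @export
simulate_bulk <- function(cfg, truth, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(truth$truth)) truth <- truth$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  types <- cell_type_names(cfg$n_cell_types)
  labels <- cfg$group_labels
  n_s <- sum(cfg$group_sizes)
  samples <- sprintf("S%02d", seq_len(n_s))
  grp <- rep(labels, cfg$group_sizes)

  with_sim_seed(cfg$seed + 1L, {
    weights <- if (is.matrix(cfg$proportions)) {
      cfg$proportions
    } else {
      w <- rdirichlet1(cfg$n_cell_types, cfg$proportions)
      cbind(w, w)
    }
    rownames(weights) <- types
    colnames(weights) <- labels

    umap <- truth$unique_marker_map
    genes <- umap$gene_symbol
    n_mk <- length(genes)
    intensity <- setNames(rlnorm(n_mk, log(5e-3), 0.8), genes)

    # plant exclusives first (need reliably detectable expression), then
    # group-different genes among the remainder; only genes of mixed-in
    # cell types are eligible, so planting never resurrects an absent type
    mixed <- types[rowSums(weights) > 0]
    pool <- genes[umap$cell_type %in% mixed]
    excl <- list()
    for (i in 1:2) {
      k <- cfg$n_exclusive_genes[i]
      if (k > length(pool)) abort("Too few eligible genes for exclusives.")
      excl[[labels[i]]] <- if (k > 0) sort(sample(pool, k)) else character()
      pool <- setdiff(pool, excl[[labels[i]]])
    }
    diff_genes <- if (cfg$n_group_diff_genes > 0) {
      sort(sample(pool, cfg$n_group_diff_genes))
    } else {
      character()
    }

    # per-gene expected proportion of the library, by group
    w_of <- function(g, grp_label) weights[umap$cell_type[match(g, genes)],
                                           grp_label]
    prop <- vapply(labels, function(lb) {
      pr <- intensity * w_of(genes, lb)
      pr[excl[[setdiff(labels, lb)]]] <- 0          # zero in the other group
      boost <- excl[[lb]]
      pr[boost] <- pmax(pr[boost], 5e-5)            # exclusives detectable
      pr[diff_genes] <- pr[diff_genes] *
        if (lb == labels[2]) 2^cfg$effect_size else 1
      pr
    }, numeric(n_mk))

    # isoform fan-out: first ceiling(fraction * n) marker genes get 2
    # transcripts splitting the gene expectation 60/40
    n_iso <- ceiling(cfg$isoform_fraction * n_mk)
    iso_genes <- genes[seq_len(n_iso)]
    tx <- bind_rows(
      tibble(gene_symbol = genes, transcript_id = paste0("T_", genes, ".1"),
             frac = ifelse(genes %in% iso_genes, 0.6, 1)),
      tibble(gene_symbol = iso_genes,
             transcript_id = paste0("T_", iso_genes, ".2"), frac = 0.4))
    tx <- arrange(tx, .data$gene_symbol, .data$transcript_id)

    # background transcripts: low lognormal expected counts, a tail below 1
    bg <- tibble(
      gene_symbol = sprintf("BG%05d", seq_len(cfg$n_background_genes)),
      transcript_id = sprintf("T_BG%05d.1", seq_len(cfg$n_background_genes)),
      bg_mu = rlnorm(cfg$n_background_genes, log(5), 2))
    # shared (ambiguous) marker genes appear in the tissue too
    sh <- tibble(gene_symbol = truth$shared_genes,
                 transcript_id = paste0("T_", truth$shared_genes, ".1"),
                 bg_mu = rlnorm(length(truth$shared_genes), log(30), 0.5))

    lib <- cfg$library_size_mean *
      rlnorm(n_s, -log(1 + cfg$library_size_cv^2) / 2,
             sqrt(log(1 + cfg$library_size_cv^2)))

    mu_marker <- sapply(seq_len(n_s), function(s) {
      pr <- prop[, grp[s]]
      lib[s] * pr[tx$gene_symbol] * tx$frac
    })
    bg_all <- bind_rows(bg, sh)
    mu_bg <- outer(bg_all$bg_mu, lib / cfg$library_size_mean)
    mu <- rbind(mu_marker, mu_bg)
    ids <- c(tx$transcript_id, bg_all$transcript_id)
    syms <- c(tx$gene_symbol, bg_all$gene_symbol)

    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / cfg$nb_dispersion),
                     nrow = nrow(mu), dimnames = list(NULL, samples))
    counts_tbl <- bind_cols(tibble(transcript_id = ids, gene_symbol = syms),
                            as_tibble(counts))
    counts_tbl <- arrange(counts_tbl, .data$transcript_id)

    counts_path <- file.path(dir, "counts.csv")
    groups_path <- file.path(dir, "groups.csv")
    write_delim_plain(counts_tbl, counts_path)
    groups_tbl <- tibble(sample_id = samples, group = grp)
    write_delim_plain(groups_tbl, groups_path)

    present <- lapply(labels, function(lb) types[weights[, lb] > 0])
    names(present) <- labels

    truth$weights <- weights
    truth$present_cell_types <- present
    truth$group_diff_genes <- diff_genes
    truth$exclusive_genes <- excl
    truth$n_transcripts <- nrow(counts_tbl)
    truth$n_marker_transcripts <- nrow(tx)
    truth$library_sizes <- setNames(lib, samples)
    list(counts_path = counts_path, groups_path = groups_path,
         truth = truth)
  })
}

#' Simulate per-sample sequencing QC metrics
#'
#' Draws total reads, average read length, mean Phred score, average depth,
#' average coverage and percent aligned from normal distributions around
#' per-group means (equal between groups unless `cfg$qc_group_means` plants a
#' difference).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory; writes `qc.csv`.
#' @return The QC metrics tibble (also written to file).
#' @export
simulate_qc <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_s <- sum(cfg$group_sizes)
  grp_i <- rep(1:2, cfg$group_sizes)
  defaults <- list(
    total_reads = list(mean = c(3e7, 3e7), sd = 3e6),
    avg_read_length = list(mean = c(95, 95), sd = 2),
    mean_phred = list(mean = c(36, 36), sd = 0.5),
    avg_depth = list(mean = c(40, 40), sd = 5),
    avg_coverage = list(mean = c(30, 30), sd = 4),
    pct_aligned = list(mean = c(85, 85), sd = 3))
  if (!is.null(cfg$qc_group_means)) {
    for (nm in names(cfg$qc_group_means)) {
      if (!nm %in% names(defaults)) {
        abort(paste0("Unknown QC metric in qc_group_means: ", nm))
      }
      defaults[[nm]]$mean <- cfg$qc_group_means[[nm]]
    }
  }
  with_sim_seed(cfg$seed + 2L, {
    out <- tibble(sample_id = sprintf("S%02d", seq_len(n_s)))
    for (nm in names(defaults)) {
      d <- defaults[[nm]]
      out[[nm]] <- round(rnorm(n_s, d$mean[grp_i], d$sd), 4)
    }
    write_delim_plain(out, file.path(dir, "qc.csv"))
    out
  })
}

#' Simulate a complete input set
#'
#' Runs [simulate_markers()], [simulate_bulk()] and [simulate_qc()] into one
#' directory and writes the combined ground truth as `truth.json`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return A list with `marker_files`, `counts_path`, `groups_path`,
#'   `qc_path`, `truth_path`, and the in-memory `truth`.
#' @export
simulate_dataset <- function(cfg, dir) {
  mk <- simulate_markers(cfg, dir)
  bk <- simulate_bulk(cfg, mk$truth, dir)
  qc <- simulate_qc(cfg, dir)
  truth <- bk$truth
  truth_path <- file.path(dir, "truth.json")
  truth_json <- truth
  truth_json$weights <- as.data.frame(truth$weights)
  jsonlite::write_json(truth_json, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  list(marker_files = mk$files,
       counts_path = bk$counts_path,
       groups_path = bk$groups_path,
       qc_path = file.path(dir, "qc.csv"),
       truth_path = truth_path,
       truth = truth)
}
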