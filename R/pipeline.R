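#' Read a pipeline configuration
#'
#' YAML with an integer `seed` plus optional overrides of [sim_params()]
#' fields and pipeline options (`n_genes`, `l_host`, `screen_coverage`, ...).
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  cfg
}

# Per-line raw variant counts in Table-1 layout
count_classes <- function(calls) {
  is_snp <- calls$vtype == "SNP"
  hom <- calls$zygosity == "hom_alt"
  c(hom_snps = sum(is_snp & hom), het_snps = sum(is_snp & !hom),
    hom_indels = sum(!is_snp & hom), het_indels = sum(!is_snp & !hom))
}

#' Depth/quality audit of per-line call sets
#'
#' Applies a filter profile, subtracts shared background polymorphisms
#' (sibling-aware), restricts to the region callable in all lines at the same
#' stringency, and back-estimates per-line and sibling-averaged T0 mutation
#' loads.
#'
#' @param callsets Named list (line -> calls data.frame).
#' @param linedata Output of [simulate_variant_calls()] (for depth tracks);
#'   alternatively supply `masks` directly.
#' @param plans Line plans.
#' @param profile A [filter_profile()].
#' @param genome_size Host genome size in bp.
#' @param masks Optional named list of per-line `IRanges` callable masks.
#' @param subtract_first Subtract shared polymorphisms before restricting to
#'   the shared-callable mask (default TRUE; the converse order is also
#'   accepted).
#' @return list: profile name, coverage fraction f, per-line table (raw
#'   counts, T0 estimates), sibling_averages, t0_grand_mean, mutation_rate,
#'   spectra (per-line SpectrumTable of homozygous SNPs), titv_average,
#'   line_specific call sets.
#' @export
audit_callsets <- function(callsets, linedata = NULL, plans, profile,
                           genome_size, masks = NULL, subtract_first = TRUE) {
  validate_line_plans(plans)
  lines <- plans$name
  if (is.null(masks)) {
    masks <- lapply(linedata, function(ld) callable_mask(ld$depth, profile))
    names(masks) <- names(linedata)
  }
  shared <- shared_callable(masks[lines], genome_size)
  filtered <- lapply(callsets[lines], filter_calls, profile = profile)
  groups <- stats::setNames(plans$sibling_group, plans$name)

  if (subtract_first) {
    part <- partition_shared(filtered, groups)
    specific <- lapply(part$line_specific, restrict_to_mask, mask = shared$mask)
  } else {
    restricted <- lapply(filtered, restrict_to_mask, mask = shared$mask)
    part <- partition_shared(restricted, groups)
    specific <- part$line_specific
  }

  per_line <- lapply(lines, function(l) {
    counts <- count_classes(specific[[l]])
    g <- plans$generation[plans$name == l]
    t0_snps <- estimate_t0_count(counts[["hom_snps"]], shared$fraction, g)
    t0_indels <- estimate_t0_count(counts[["hom_indels"]], shared$fraction, g)
    t0_total <- estimate_t0_total(counts[["hom_snps"]], counts[["hom_indels"]],
                                  shared$fraction, g)
    data.frame(line = l, generation = g, t(counts),
               total_raw = sum(counts),
               t0_snps = t0_snps$rounded, t0_indels = t0_indels$rounded,
               t0_total = t0_total$rounded,
               t0_total_unrounded = t0_total$estimate,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_line)

  sib <- vapply(split(tab$t0_total_unrounded, groups[tab$line]),
                function(x) sibling_average(x)$estimate, numeric(1))
  grand <- mean(sib)
  spectra <- lapply(lines, function(l) {
    s <- specific[[l]]
    spectrum_table(s[s$vtype == "SNP" & s$zygosity == "hom_alt", , drop = FALSE])
  })
  names(spectra) <- lines

  list(profile = profile$name,
       coverage_fraction = shared$fraction,
       table = tab,
       sibling_averages = round_half_up(sib),
       t0_grand_mean = grand,
       mutation_rate = mutation_rate(grand, genome_size),
       spectra = spectra,
       titv_average = tryCatch(titv_average(spectra), error = function(e) NA_real_),
       background = part$background,
       line_specific = specific,
       shared_mask = shared$mask)
}

cgh_zygosity_pair <- function(m1, m2, tol = 0.3) {
  d <- m1 - m2
  if (abs(d - 1) <= tol) c("homozygous", "heterozygous")
  else if (abs(d + 1) <= tol) c("heterozygous", "homozygous")
  else if (abs(d) <= tol) c("same_dose", "same_dose")
  else c("indeterminate", "indeterminate")
}

#' Run the full molecular-characterization pipeline on synthetic data
#'
#' Stages: simulate (reference, truth, calls, reads, array) -> CAPS
#' genotyping -> exogenous-sequence screen -> CGH analysis -> variant audit
#' (per filter profile) -> effect annotation -> T0 estimation -> report.
#' Every stage draws its randomness from seeds derived from `config$seed`,
#' so a repeated run is identical.
#'
#' @param config Named list (or YAML path) with `seed` and optional
#'   overrides: any [sim_params()] field, plus `screen_coverage` (fold
#'   coverage of screening reads, default 5), `cgh_host_region_bp` (default
#'   6000), `upstream_window`/`downstream_window` (default 5000), `out_dir`
#'   (write artifacts when set), `annotate` (default TRUE).
#' @return An `AuditReport` list.
#' @export
run_pipeline <- function(config = list(seed = 1L)) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  opts <- config[names(config) %in% c("out_dir", "screen_coverage",
                                      "cgh_host_region_bp", "upstream_window",
                                      "downstream_window", "annotate",
                                      "n_t0_mutations_per_group")]
  par_over <- config[!(names(config) %in% c(names(opts)))]
  params <- do.call(sim_params, par_over)
  screen_coverage <- opts$screen_coverage %||% 5
  cgh_bp <- opts$cgh_host_region_bp %||% 6000L
  upw <- opts$upstream_window %||% 5000L
  dnw <- opts$downstream_window %||% 5000L
  do_annotate <- opts$annotate %||% TRUE
  n_t0 <- opts$n_t0_mutations_per_group %||% params$n_t0_mutations

  ## simulate
  ref <- generate_reference(params)
  plans <- default_line_plans(insertion_site = min(params$l_host - 1000L, 50000L))
  groups <- unique(plans$sibling_group)
  truth <- empty_truth()
  for (i in seq_along(groups)) {
    truth <- rbind(truth, induce_t0_mutations(
      ref, n_t0, params$spectrum_weights, params$indel_fraction,
      group = groups[i], seed = params$seed + 10L + i, avoid = truth$pos))
  }
  truth <- rbind(truth, background_polymorphisms(
    ref, params$n_background_polymorphisms, params$spectrum_weights,
    seed = params$seed + 20L, avoid = truth$pos))
  truth <- segregate(truth, plans, seed = params$seed + 30L)
  linedata <- simulate_variant_calls(truth, plans, params)

  ## caps
  fixture <- caps_fixture(seed = params$seed + 40L)
  caps <- lapply(plans$name, function(l) {
    # every study line carries the GT edit; the assay itself distinguishes
    # WT / het / homo templates
    a1 <- digest(extract_amplicon(fixture$template_gt, fixture$fwd_primer,
                                  fixture$rev_primer))
    a2 <- a1
    list(genotype = caps_genotype(a1, a2), fragments = a1$fragments)
  })
  names(caps) <- plans$name

  ## exogenous screen
  refs <- c(list(vector_backbone = substr(ref$vector, ref$backbone[1],
                                          ref$backbone[2]),
                 t_dna = substr(ref$vector, ref$t_dna[1], ref$t_dna[2])),
            ref$foreign_panel)
  screens <- list(); screen_reads_by_line <- list()
  for (i in seq_len(nrow(plans))) {
    l <- plans$name[i]
    haps <- line_haplotypes(ref, plans[i, ])
    n_reads <- ceiling(screen_coverage * nchar(haps[1]) / params$read_length)
    rd <- simulate_reads_diploid(haps, n_reads, params$read_length,
                                 params$base_error_rate,
                                 seed = params$seed + 50L + i)
    rd <- qc_reads(rd)
    screen_reads_by_line[[l]] <- rd
    screens[[l]] <- screen_reads(rd, refs, ref$host)
  }

  ## cgh
  host_region <- substr(ref$host, 1L, cgh_bp)
  probes <- design_probes(host_region, ref$vector)
  vecp <- probes$source %in% c("vector_forward", "vector_reverse")
  dose <- c(none = 0, het = 1, homo = 2)
  cgh <- list()
  for (i in seq_len(nrow(plans))) {
    l <- plans$name[i]
    copies_test <- ifelse(vecp, dose[[plans$vector_insertion[i]]],
                          ifelse(probes$source == "host_region", 2, 2))
    copies_ref <- ifelse(vecp, 0, 2)
    raw <- simulate_cgh(probes, copies_test, copies_ref,
                        within_seed(params, params$seed + 60L + i))
    arr <- normalize_and_ratio(raw)
    vec_track <- arr$log2_ratio[vecp]
    sm <- moving_average(vec_track, 20L)
    ab <- call_aberrations(sm)
    cgh[[l]] <- list(mean_vector_log2 = mean(vec_track),
                     aberrations = ab,
                     verdict = if (nrow(ab) > 0) "present" else "absent")
  }
  carriers <- plans$name[plans$vector_insertion != "none"]
  if (length(carriers) == 2) {
    z <- cgh_zygosity_pair(cgh[[carriers[1]]]$mean_vector_log2,
                           cgh[[carriers[2]]]$mean_vector_log2)
    cgh[[carriers[1]]]$copy_state <- z[1]
    cgh[[carriers[2]]]$copy_state <- z[2]
  }
  for (l in setdiff(plans$name, carriers)) cgh[[l]]$copy_state <- "absent"

  ## audit per profile
  callsets <- lapply(linedata, `[[`, "calls")
  audits <- list(
    DP2Q10 = audit_callsets(callsets, linedata, plans, filter_profile("DP2Q10"),
                            params$l_host),
    DP4Q20 = audit_callsets(callsets, linedata, plans, filter_profile("DP4Q20"),
                            params$l_host))

  ## effects
  effects <- NULL
  if (isTRUE(do_annotate)) {
    effects <- lapply(plans$name, function(l) {
      vs <- audits$DP2Q10$line_specific[[l]]
      if (nrow(vs) == 0)
        return(list(tally = tally_effects(data.frame(category = character(0))),
                    impactful = 0L))
      recs <- annotate_variants(vs, ref$gene_models, ref$host, upw, dnw)
      t <- tally_effects(recs)
      list(tally = t, impactful = impactful_count(t))
    })
    names(effects) <- plans$name
  }

  ## validation-style consistency check (hom vs het SNP counts at DP2Q10)
  consistency <- lapply(seq_len(nrow(plans)), function(i) {
    l <- plans$name[i]
    s <- audits$DP2Q10$line_specific[[l]]
    consistency_ratio(sum(s$vtype == "SNP" & s$zygosity == "hom_alt"),
                      sum(s$vtype == "SNP" & s$zygosity == "het"),
                      plans$generation[i])
  })
  names(consistency) <- plans$name

  report <- structure(list(
    seed = params$seed,
    params = params,
    plans = plans,
    truth_summary = table(truth$origin),
    depth_peaks = vapply(linedata, function(ld) depth_peak(ld$depth), integer(1)),
    caps = caps,
    screen = screens,
    cgh = cgh,
    audits = audits,
    effects = effects,
    consistency = consistency
  ), class = "AuditReport")

  if (!is.null(opts$out_dir))
    write_report_artifacts(report, ref, truth, linedata, probes,
                           screen_reads_by_line, opts$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

within_seed <- function(params, seed) { params$seed <- seed; params }

# Write the pipeline's file artifacts (FASTA/GFF3/VCF/BED/FASTQ/TSV).
write_report_artifacts <- function(report, ref, truth, linedata, probes,
                                   screen_reads_by_line, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(chr1 = ref$host), file.path(out_dir, "host.fasta"))
  write_fasta(c(vector = ref$vector), file.path(out_dir, "vector.fasta"))
  write_fasta(ref$foreign_panel, file.path(out_dir, "foreign_panel.fasta"))
  write_gff3(ref$gene_models, file.path(out_dir, "genes.gff3"))
  write_tsv_file(truth, file.path(out_dir, "truth.tsv"))
  write_tsv_file(probes, file.path(out_dir, "probes.tsv"))
  for (l in names(linedata)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", l)
    write_vcf(linedata[[l]]$calls,
              file.path(out_dir, paste0(safe, ".vcf.gz")), sample = l)
    write_bed(callable_mask(linedata[[l]]$depth, filter_profile("DP2Q10")),
              file.path(out_dir, paste0(safe, ".DP2Q10.callable.bed")))
    write_fastq(screen_reads_by_line[[l]],
                file.path(out_dir, paste0(safe, ".fastq")))
  }
  for (p in names(report$audits))
    write_tsv_file(report$audits[[p]]$table,
                   file.path(out_dir, paste0("table1_", p, ".tsv")))
  invisible(out_dir)
}
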