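write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the full analysis pipeline
#'
#' Orchestrates the whole inference chain on one input bundle:
#' per-individual classification of clones into basic sequences, somatic
#' variants and recombinants (cDNA, and gDNA when present, with a
#' cDNA/gDNA cross-check); somatic mutation and recombination rates;
#' domain-partitioned diversity tables for the whole clone sample and
#' for the basic sequences only (the somatic layer distorts evolutionary
#' statistics, so both views are first-class); intron population
#' analysis from a peak table; and family segregation analysis. Outputs
#' are written as TSV/JSON/FASTA under `out_dir`; missing optional
#' inputs skip their stage with a message.
#'
#' @param alignment Path to an aligned FASTA, or a [clone_alignment].
#' @param reference_id Reference header (when `alignment` is a path).
#' @param classes_path Column-class sidecar TSV (when needed).
#' @param peaks_path Optional population peak TSV
#'   (individual/intron/size, optional population column).
#' @param family_path Optional family peak TSV
#'   (family/member/intron/size).
#' @param out_dir Output directory.
#' @param tau,min_support,min_run,max_mismatch Classification parameters.
#' @param deletion Deletion policy for pi.
#' @param partition Domain partition.
#' @return Invisibly, a list with all stage results and `errors`.
#' @export
run_full_analysis <- function(alignment, reference_id = NULL,
                              classes_path = NULL, peaks_path = NULL,
                              family_path = NULL, out_dir = "ampliclone_out",
                              tau = 3L, min_support = 2L, min_run = 2L,
                              max_mismatch = 2L, deletion = "complete",
                              partition = default_partition()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  report <- list()
  note <- function(fmt, ...) message(sprintf(fmt, ...))

  aln <- if (inherits(alignment, "clone_alignment")) alignment
  else read_alignment(alignment, reference_id, classes_path)
  report$n_sequences <- nrow(aln$mat)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", name, conditionMessage(e)))
      note("stage '%s' failed: %s", name, conditionMessage(e))
      NULL
    })
  }

  # --- classification -------------------------------------------------
  report$classification <- stage("classification", {
    out <- list()
    for (src in intersect(c("cDNA", "gDNA"), unique(aln$info$source))) {
      cls <- classify_individuals(aln, source = src, tau = tau,
                                  min_support = min_support,
                                  min_run = min_run,
                                  max_mismatch = max_mismatch)
      out[[src]] <- cls
      va <- annotate_variants(cls, partition)
      va$pos_1based <- va$position + 1L
      write.table(va[, c("individual", "clone_id", "pos_1based",
                         "basic_state", "clone_state", "occurrence",
                         "effect", "domain")],
                  file.path(out_dir, sprintf("variants_%s.tsv", src)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      rec_rows <- do.call(rbind, lapply(cls, function(bs)
        if (length(bs$recombinants))
          data.frame(individual = bs$individual_id,
                     clone = vapply(bs$recombinants, `[[`, "", "clone_id"),
                     donors = vapply(bs$recombinants, function(r)
                       paste(r$donors, collapse = "+"), ""),
                     breakpoint_start = vapply(bs$recombinants, function(r)
                       r$breakpoints[1L, 1L] + 1L, 0L),
                     breakpoint_end = vapply(bs$recombinants, function(r)
                       r$breakpoints[1L, 2L] + 1L, 0L))
        else NULL))
      if (is.null(rec_rows)) rec_rows <-
          data.frame(individual = character(0), clone = character(0),
                     donors = character(0), breakpoint_start = integer(0),
                     breakpoint_end = integer(0))
      write.table(rec_rows,
                  file.path(out_dir, sprintf("recombinants_%s.tsv", src)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fa <- unlist(lapply(cls, function(bs)
        setNames(bs$basics, sprintf("%s_basic%d",
                                    bs$individual_id,
                                    seq_along(bs$basics)))))
      writeLines(paste0(">", names(fa), "\n", fa),
                 file.path(out_dir, sprintf("basics_%s.fasta", src)))
    }
    out
  })

  report$rates <- stage("rates", {
    cls <- report$classification$cDNA
    if (is.null(cls)) stop("no cDNA classification available")
    n_sites <- nchar(cls[[1L]]$basics[1L])
    mu <- somatic_mutation_rate(cls, n_sites)
    rho <- recombination_rate(cls)
    rates <- list(mutation_rate = mu$rate,
                  mutation_numerator = mu$numerator,
                  mutation_denominator = mu$denominator,
                  recombination_mean = rho$mean, recombination_se = rho$se,
                  recombination_fractions = as.list(rho$fractions))
    write_json_file(rates, file.path(out_dir, "rates.json"))
    rates
  })

  report$crosscheck <- stage("crosscheck", {
    cls <- report$classification
    if (is.null(cls$cDNA) || is.null(cls$gDNA)) return(NULL)
    shared <- intersect(names(cls$cDNA), names(cls$gDNA))
    out <- lapply(shared, function(iv)
      crosscheck_gdna_cdna(cls$cDNA[[iv]], cls$gDNA[[iv]]))
    names(out) <- shared
    write_json_file(lapply(out, function(x)
      x[c("individual", "cdna_only", "gdna_only", "shared_variants")]),
      file.path(out_dir, "crosscheck.json"))
    out
  })

  # --- diversity tables ----------------------------------------------
  report$diversity <- stage("diversity", {
    cod <- if (!is.null(aln$classes)) extract_region(aln, "coding") else aln
    sets <- list()
    cdna_rows <- which(cod$info$source == "cDNA" |
                         rownames(cod$mat) == "ref_cDNA")
    if (length(cdna_rows) >= 2L)
      sets$all <- subset_clones(cod, cdna_rows)
    cls <- report$classification$cDNA
    if (!is.null(cls)) {
      fa <- unlist(lapply(cls, `[[`, "basics"))
      ref_row <- which(rownames(cod$mat) == "ref_cDNA")
      if (length(ref_row))
        fa <- c(fa, ref_cDNA = paste(cod$mat[ref_row, ], collapse = ""))
      bm <- t(vapply(fa, function(s) strsplit(s, "")[[1L]],
                     character(nchar(fa[1L]))))
      rownames(bm) <- make.unique(names(fa))
      info <- data.frame(id = rownames(bm), individual = NA, clone = NA,
                         source = NA)
      sets$basic <- clone_alignment(bm, info, rownames(bm)[1L])
    }
    tabs <- NULL
    for (set_name in names(sets)) {
      sub <- sets[[set_name]]
      regs <- list(signal = extract_region(sub, "signal", partition),
                   mature = extract_region(sub, "mature", partition),
                   cterm = extract_region(sub, "cterm", partition),
                   all = sub)
      for (rn in names(regs)) {
        row <- diversity_stats(regs[[rn]], region = rn,
                               deletion = deletion, kaks = TRUE)
        row$sequence_set <- set_name
        tabs <- rbind(tabs, row)
      }
    }
    write.table(format(tabs, digits = 5),
                file.path(out_dir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sets$basic))
      write_json_file(list(rm_basic = hudson_kaplan_rm(sets$basic)$rm),
                      file.path(out_dir, "rm.json"))
    tabs
  })

  # --- population stage ----------------------------------------------
  if (!is.null(peaks_path) && file.exists(peaks_path)) {
    report$population <- stage("population", {
      peaks <- read_peaks(peaks_path)
      if (!"population" %in% names(peaks)) peaks$population <- "pop"
      out <- list(); freq_rows <- NULL; div_rows <- NULL
      for (popname in unique(peaks$population))
        for (intr in unique(peaks$intron)) {
          sub <- peaks[peaks$population == popname & peaks$intron == intr, ]
          if (!nrow(sub)) next
          ps <- population_sample(sub, intron = intr, name = popname)
          li <- locus_inference(ps)
          out[[sprintf("%s_intron%s", popname, intr)]] <- li
          fr <- allele_frequencies(ps)
          freq_rows <- rbind(freq_rows,
                             data.frame(population = popname, intron = intr,
                                        size = names(fr),
                                        frequency = as.numeric(fr)))
          div_rows <- rbind(div_rows,
                            data.frame(population = popname, intron = intr,
                                       A = li$A,
                                       gene_diversity = li$gene_diversity))
        }
      write.table(freq_rows, file.path(out_dir, "freqs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(div_rows, file.path(out_dir, "population_diversity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_file(out, file.path(out_dir, "locus_inference.json"))
      pops <- unique(peaks$population)
      if (length(pops) == 2L) {
        wmw <- lapply(unique(peaks$intron), function(intr) {
          a <- population_sample(peaks[peaks$population == pops[1L] &
                                         peaks$intron == intr, ],
                                 intron = intr, name = pops[1L])
          b <- population_sample(peaks[peaks$population == pops[2L] &
                                         peaks$intron == intr, ],
                                 intron = intr, name = pops[2L])
          c(list(intron = intr), compare_populations_wmw(a, b))
        })
        write_json_file(wmw, file.path(out_dir, "wmw.json"))
        out$wmw <- wmw
      }
      out
    })
  } else message("no peak table: population stage skipped")

  # --- family stage ---------------------------------------------------
  if (!is.null(family_path) && file.exists(family_path)) {
    report$family <- stage("family", {
      peaks <- read_family_peaks(family_path)
      out <- list()
      for (fam in unique(peaks$family)) {
        cross <- family_cross(peaks[peaks$family == fam, ])
        introns <- names(cross$father)
        blocks <- lapply(introns, function(intr)
          suppressWarnings(infer_parental_haplotypes(cross, intr)))
        names(blocks) <- introns
        seg <- lapply(introns, function(intr) {
          gc <- genotype_class_counts(cross, blocks[[intr]], intr)
          cs <- chi_square_segregation(as.vector(gc$counts))
          list(intron = intr, observed = as.vector(gc$counts),
               chi2 = cs$chi2, df = cs$df, p = cs$p)
        })
        linkage <- if (length(introns) >= 2L)
          test_intron_linkage(cross, blocks[[introns[1L]]],
                              blocks[[introns[2L]]], introns[1:2])
        else NULL
        verdict <- fit_locus_model(cross, blocks)
        out[[fam]] <- list(blocks = blocks, segregation = seg,
                           linkage = linkage, verdict = verdict)
      }
      write_json_file(lapply(out, function(x) list(
        verdict = x$verdict$verdict,
        complete_disequilibrium =
          if (!is.null(x$linkage)) x$linkage$complete_disequilibrium else NA,
        segregation = x$segregation)),
        file.path(out_dir, "family.json"))
      out
    })
  } else message("no family table: family stage skipped")

  report$errors <- errors
  if (length(errors))
    warning(sprintf("%d stage(s) failed: %s", length(errors),
                    paste(errors, collapse = "; ")))
  invisible(report)
}
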