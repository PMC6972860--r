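#' Pipeline configuration
#'
#' Paths, stage toggles and stage parameters for [run_pipeline()]. A
#' configuration can also be read from a YAML file with
#' [read_pipeline_config()]; explicitly supplied arguments win over file
#' values, and the effective configuration is echoed into the report.
#'
#' @param assembly FASTA path of the assembly to curate (required).
#' @param alignments SAM/BAM/PAF path of reads mapped to `assembly`
#'   (required for the junction stage and for coverage reporting).
#' @param classifier Kaiju-style 3-column TSV of per-fragment
#'   classifications (required for the decontamination stage).
#' @param taxonomy Taxonomy file (nodes.dmp-style or 4-column TSV).
#' @param taxonomy_names Optional names.dmp when `taxonomy` is a nodes.dmp.
#' @param mito_reference FASTA of a mitochondrial reference genome
#'   (required for the mito stage).
#' @param mito_anchor Optional FASTA of the start anchor (e.g. the large
#'   subunit rRNA gene); without it the mito contig is trimmed but not
#'   rotated.
#' @param rdna_annotation Optional BED/GFF3 with the rDNA operon interval
#'   (enables the copy-number stage).
#' @param outdir Output directory (created).
#' @param stages Character vector among
#'   `c("junctions", "decontam", "mito", "rdna", "stats")`.
#' @param junction_params A [junction_params()].
#' @param min_piece Minimum piece length kept after breaking.
#' @param window Fragmentation window for screening lookups.
#' @param seed Integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(assembly, alignments = NULL, classifier = NULL,
                            taxonomy = NULL, taxonomy_names = NULL,
                            mito_reference = NULL, mito_anchor = NULL,
                            rdna_annotation = NULL, outdir = "crcurate-out",
                            stages = c("junctions", "decontam", "mito",
                                       "stats"),
                            junction_params = crcurate::junction_params(),
                            min_piece = 1000, window = 500, seed = 42) {
  cfg <- list(assembly = assembly, alignments = alignments,
              classifier = classifier, taxonomy = taxonomy,
              taxonomy_names = taxonomy_names,
              mito_reference = mito_reference, mito_anchor = mito_anchor,
              rdna_annotation = rdna_annotation, outdir = outdir,
              stages = stages, junction_params = junction_params,
              min_piece = min_piece, window = window,
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("junctions", "decontam", "mito", "rdna", "stats")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need <- function(field, stage)
    if (stage %in% cfg$stages && is.null(cfg[[field]]))
      stop("stage '", stage, "' requires config field '", field, "'")
  if (!file.exists(cfg$assembly)) stop("assembly not found: ", cfg$assembly)
  need("alignments", "junctions")
  need("classifier", "decontam"); need("taxonomy", "decontam")
  need("mito_reference", "mito")
  need("alignments", "rdna"); need("rdna_annotation", "rdna")
  for (f in c("alignments", "classifier", "taxonomy", "mito_reference",
              "mito_anchor", "rdna_annotation")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config file not found: ", cfg[[f]])
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipeline_config()]
#'   arguments (`junction_params` as a mapping of `a`..`f`).
#' @param ... Overrides; explicitly supplied arguments win over the file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$junction_params))
    y$junction_params <- do.call(junction_params, y$junction_params)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

#' Run the end-to-end curation pipeline
#'
#' Stage order mirrors the curation of the original assemblies: per-base
#' depth from the supplied alignments, junction breaking at unexpected
#' coverage drops, taxonomic decontamination, mitochondrial contig
#' curation, and summary statistics; each stage reads the previous stage's
#' contig set. Disabled stages pass the contigs through. Screening uses
#' the classifier fragments of the *input* assembly; after breaking,
#' pieces inherit the verdict of their source contig. All stage outputs
#' are persisted under `outdir` and every report number is recomputable
#' from them.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `curation_report` (list of per-stage summaries), invisibly
#'   written to `outdir/report.json` and `outdir/report.txt`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[crcurate] ", ...)
  report <- list(tool = "crcurate",
                 version = as.character(utils::packageVersion("crcurate")),
                 parameters = config_as_list(config),
                 timestamp = format(Sys.time(), tz = "UTC"))
  contigs <- Biostrings::readDNAStringSet(config$assembly)
  input_names <- names(contigs) <- sub("\\s.*", "", names(contigs))
  source_of <- setNames(input_names, input_names)

  tracks <- NULL
  if (!is.null(config$alignments)) {
    say("computing per-base depth from ", config$alignments)
    tracks <- depth_from_alignments(config$alignments,
                                    contigs = setNames(
                                      Biostrings::width(contigs),
                                      names(contigs)))
  }

  if ("junctions" %in% config$stages) {
    say("detecting coverage-drop junctions")
    calls <- detect_junctions(tracks, config$junction_params)
    broken <- break_contigs(contigs, calls, config$min_piece)
    tracks <- break_tracks(tracks, calls, config$min_piece)
    nm <- names(broken$contigs)
    source_of <- setNames(
      ifelse(nm %in% input_names, nm, sub("\\.[0-9]+$", "", nm)), nm)
    contigs <- broken$contigs
    write_fasta(contigs, file.path(config$outdir, "01_broken.fasta"))
    write_bed(broken$removed, file.path(config$outdir, "removed.bed"))
    report$junctions <- list(n_calls = nrow(calls),
                             n_contigs_cut =
                               length(unique(calls$contig)),
                             n_pieces_dropped = nrow(broken$dropped),
                             removed_bp = sum(broken$removed$end -
                                              broken$removed$start))
  }

  if ("decontam" %in% config$stages) {
    say("screening contigs for contamination")
    tree <- read_taxonomy(config$taxonomy, config$taxonomy_names)
    cov <- if (!is.null(tracks)) median_contig_coverage(tracks) else NULL
    # fragments were classified on the input assembly; aggregate verdicts
    # on the source contigs, pieces inherit their source's verdict
    cl <- read.table(config$classifier, sep = "\t", header = FALSE,
                     col.names = c("status", "fragment_id", "taxid"))
    cl_contig <- sub(":[0-9]+-[0-9]+$", "", cl$fragment_id)
    cl <- cl[cl_contig %in% source_of, , drop = FALSE]
    src_cov <- NULL
    if (!is.null(cov)) {
      src_cov <- tapply(cov, source_of[names(cov)], stats::median)
      src_cov <- setNames(as.numeric(src_cov), names(src_cov))
    }
    src_set <- unique(source_of)
    src_contigs <- Biostrings::readDNAStringSet(config$assembly)
    names(src_contigs) <- sub("\\s.*", "", names(src_contigs))
    screens <- screen_contigs(src_contigs[src_set], cl, tree,
                              coverage = src_cov)
    verdict <- setNames(screens$verdict, screens$contig)
    keep <- verdict[source_of[names(contigs)]] == "keep"
    kept <- contigs[keep]; dropped <- contigs[!keep]
    write_fasta(kept, file.path(config$outdir, "02_kept.fasta"))
    write_fasta(dropped, file.path(config$outdir, "02_dropped.fasta"))
    write_screen_tsv(screens, file.path(config$outdir, "screen.tsv"))
    report$decontam <- list(n_screened = nrow(screens),
                            n_dropped_contigs = sum(!keep),
                            dropped = unname(names(dropped)))
    contigs <- kept
  }

  if ("mito" %in% config$stages) {
    say("curating the mitochondrial contig")
    ref <- Biostrings::readDNAStringSet(config$mito_reference)
    hit <- identify_mito_contig(contigs, ref)
    trim <- circ_trim(contigs[hit$contig])
    cur <- trim$curation
    mito <- trim$contig
    if (!is.null(config$mito_anchor)) {
      rs <- circ_restart(mito, config$mito_anchor)
      mito <- rs$contig
      cur$rotation_offset <- rs$curation$rotation_offset
      cur$strand_flipped <- rs$curation$strand_flipped
    }
    names(mito) <- paste0(hit$contig, "_mito")
    write_fasta(mito, file.path(config$outdir, "03_mito.fasta"))
    contigs <- c(contigs[setdiff(names(contigs), hit$contig)], mito)
    report$mito <- list(contig = hit$contig,
                        containment = hit$containment,
                        overlap_trimmed = cur$overlap_trimmed,
                        rotation_offset = cur$rotation_offset,
                        strand_flipped = cur$strand_flipped,
                        final_length = cur$final_length)
  }

  if ("rdna" %in% config$stages) {
    say("estimating rDNA operon copy number")
    iv <- read_intervals(config$rdna_annotation)
    op <- iv[iv$name %in% c("operon", "rDNA", ""), , drop = FALSE]
    if (nrow(op) == 0) op <- iv[1, , drop = FALSE]
    ann <- operon_annotation(op$contig[1], op$start[1], op$end[1])
    cn <- operon_copy_number(tracks, ann)
    report$rdna <- list(haploid_copies = cn$haploid_copies,
                        operon_median_depth = cn$operon_median_depth,
                        backbone_median_depth = cn$backbone_median_depth)
  }

  final_path <- file.path(config$outdir, "final.fasta")
  write_fasta(contigs, final_path)
  if ("stats" %in% config$stages) {
    st <- assembly_stats(contigs)
    report$stats <- list(n_contigs = st$n_contigs, total_bp = st$total_bp,
                         n50 = st$n50, gc_percent = st$gc_percent)
  }
  class(report) <- "curation_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(config$outdir, "report.txt"))
  say("done; outputs in ", config$outdir)
  invisible(report)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$junction_params <- unclass(out$junction_params)
  out
}

format_report <- function(r) {
  lines <- c(sprintf("crcurate %s curation report (%s)", r$version,
                     r$timestamp))
  if (!is.null(r$junctions))
    lines <- c(lines, sprintf(
      "junctions: %d calls on %d contigs, %d bp removed, %d pieces dropped",
      r$junctions$n_calls, r$junctions$n_contigs_cut,
      r$junctions$removed_bp, r$junctions$n_pieces_dropped))
  if (!is.null(r$decontam))
    lines <- c(lines, sprintf(
      "decontamination: %d screened, %d contigs dropped",
      r$decontam$n_screened, r$decontam$n_dropped_contigs))
  if (!is.null(r$mito))
    lines <- c(lines, sprintf(
      "mitochondrion: %s (containment %.2f), trimmed %d bp, final %d bp",
      r$mito$contig, r$mito$containment, r$mito$overlap_trimmed,
      r$mito$final_length))
  if (!is.null(r$rdna))
    lines <- c(lines, sprintf("rDNA operon: %.1f haploid copies",
                              r$rdna$haploid_copies))
  if (!is.null(r$stats))
    lines <- c(lines, sprintf(
      "final assembly: %d contigs, %.0f bp, N50 %.0f, GC %.1f%%",
      r$stats$n_contigs, r$stats$total_bp, r$stats$n50,
      r$stats$gc_percent))
  lines
}

#' @export
print.curation_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
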