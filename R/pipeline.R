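# Config-driven staged runner tying the pipeline together. The config is a
# flat named list (or a key=value text file); stages run in the order given,
# every input file is checked before any stage runs, every output TSV
# carries a provenance header, and a structured log records per-filter
# attrition counts.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line: ",
                                  lines[which(lengths(kv) != 3)[1]])
  setNames(lapply(kv, function(m) trimws(m[3])), trimws(vapply(kv, `[`, "", 2)))
}

#' Run pipeline stages from a configuration
#'
#' Supported stages (comma-separated in `config$stages`, run in order):
#' \describe{
#'   \item{simulate-splash}{generate a chimeric library
#'     (`ref_length`, `n_reads`, `noise_fraction`, `duplicate_rate`,
#'     `interactions` as `a1s-a1e:a2s-a2e:w;...`, `seed`) and write
#'     `splash_reads.sam`.}
#'   \item{splash}{`sam` + `layout_tsv` (+ optional `regions_tsv`) ->
#'     `interactions.tsv`, `categories.tsv`, `arcs.tsv`.}
#'   \item{reactivity}{`mod_sam`, `unt_sam`, `den_sam`, `ref_fasta`
#'     (+ `min_depth`) -> `reactivity_profile.tsv`.}
#'   \item{n60}{`reads_fasta`, `flank5`, `flank3` (+ `insert_length`) ->
#'     `inserts.tsv`, `pfm.tsv`.}
#'   \item{variants}{`pileups` (comma-separated TSVs), `ref_fasta`
#'     (+ `min_var_freq`, `error_rate`, `alpha`) -> per-sample
#'     `variants_<k>.tsv` and `variants_intersect.tsv`.}
#' }
#'
#' All declared input files are checked before any stage runs (missing input
#' fails pre-flight, leaving no partial outputs). A `pipeline.log` with one
#' line per stage, including filter attrition counts, is written to the
#' output directory.
#'
#' @param config named list, or path to a key=value config file. Must
#'   contain `stages` and `out_dir`.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stages <- strsplit(config$stages %||% stop("config needs 'stages'"), ",")[[1]]
  stages <- trimws(stages)
  out_dir <- config$out_dir %||% stop("config needs 'out_dir'")

  input_keys <- list(
    splash = c("sam", "layout_tsv"),
    reactivity = c("mod_sam", "unt_sam", "den_sam", "ref_fasta"),
    n60 = "reads_fasta",
    variants = c("ref_fasta")
  )
  # pre-flight: every declared input must exist before any stage runs
  generated <- character(0)
  for (st in stages) {
    if (st == "simulate-splash") {
      generated <- c(generated, file.path(out_dir, "splash_reads.sam"))
      next
    }
    if (!st %in% names(input_keys)) stop("unknown stage: ", st)
    paths <- unlist(config[input_keys[[st]]], use.names = FALSE)
    if (st == "variants")
      paths <- c(paths, strsplit(config$pileups %||% "", ",")[[1]])
    if (st == "splash" && !is.null(config$regions_tsv))
      paths <- c(paths, config$regions_tsv)
    missing <- setdiff(paths[nzchar(paths)], generated)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logln <- function(...) writeLines(sprintf(...), log_con)

  num <- function(key, default) as.numeric(config[[key]] %||% default)

  for (st in stages) {
    if (st == "simulate-splash") {
      interactions <- lapply(strsplit(config$interactions, ";")[[1]], function(s) {
        v <- as.numeric(strsplit(s, "[:-]")[[1]])
        list(arm1 = v[1:2], arm2 = v[3:4], weight = v[5])
      })
      recs <- simulate_chimeric_library(
        ref_length = num("ref_length", 600),
        interactions = interactions,
        n_reads = num("n_reads", 500),
        noise_fraction = num("noise_fraction", 0.1),
        duplicate_rate = num("duplicate_rate", 0),
        n_linear = num("n_linear", 100),
        seed = as.integer(config$seed %||% stop("simulate-splash needs 'seed'")))
      sam_path <- file.path(out_dir, "splash_reads.sam")
      write_sam(recs, sam_path,
                setNames(as.integer(num("ref_length", 600)), "precursor"))
      logln("simulate-splash: wrote %d records to %s", nrow(recs), sam_path)
      if (is.null(config$sam)) config$sam <- sam_path
    } else if (st == "splash") {
      recs <- read_sam(config$sam)
      layout <- read_pie_layout(config$layout_tsv)
      dd <- dedupe_reads(recs)
      cs <- extract_chimeras(dd)
      fs <- filter_chimeras(cs, layout,
                            min_mapq = num("min_mapq", 20),
                            min_arm_span = num("min_arm", 10))
      map <- bin_and_normalize(fs, window_size = num("window", 10))
      write_tsv_provenance(map$counts, file.path(out_dir, "interactions.tsv"),
                           config[c("window", "min_mapq", "min_arm")])
      write_tsv_provenance(arc_coordinates(map), file.path(out_dir, "arcs.tsv"))
      logln(paste0("splash: %d records in, %d after dedup (-%d), %d chimeras, ",
                   "%d after filters (-%d mapq, -%d span, -%d junction), ",
                   "%d window pairs, total_mapped %d"),
            nrow(recs), nrow(dd), attr(dd, "n_removed"),
            nrow(cs$chimeras), nrow(fs$chimeras),
            attr(fs, "n_removed_mapq"), attr(fs, "n_removed_span"),
            attr(fs, "n_removed_junction"), nrow(map$counts), map$total_mapped)
      if (!is.null(config$regions_tsv)) {
        regions <- utils::read.table(config$regions_tsv, sep = "\t",
                                     header = TRUE, comment.char = "#",
                                     stringsAsFactors = FALSE)$label
        cl <- classify_interactions(map, regions)
        write_tsv_provenance(cl$aggregates, file.path(out_dir, "categories.tsv"))
        logln("splash: classified %d pairs into categories", nrow(cl$pairs))
      }
    } else if (st == "reactivity") {
      ref <- read_fasta(config$ref_fasta)
      thr <- num("min_depth", 500)
      mc <- lapply(c(mod = "mod_sam", unt = "unt_sam", den = "den_sam"),
                   function(k) count_mutation_rates(read_sam(config[[k]]), ref[1]))
      prof <- compute_reactivity(mc$mod, mc$unt, mc$den, depth_threshold = thr)
      prof <- tryCatch(normalize_reactivity(prof), error = function(e) prof)
      write_reactivity_tsv(prof, file.path(out_dir, "reactivity_profile.tsv"))
      logln("reactivity: %d positions, %d unmasked at depth >= %d",
            length(prof$raw), sum(prof$mask), thr)
    } else if (st == "n60") {
      reads <- read_fasta(config$reads_fasta)
      lib <- extract_inserts(unname(reads), config$flank5, config$flank3,
                             expected_length = num("insert_length", 60))
      write_tsv_provenance(data.frame(insert = lib$inserts),
                           file.path(out_dir, "inserts.tsv"),
                           config[c("flank5", "flank3")])
      if (lib$n_retained) {
        pfm <- build_pfm(lib)
        write_tsv_provenance(
          data.frame(position = seq_len(ncol(pfm$counts)) - 1L,
                     t(pfm$frequencies),
                     information_content = pfm$information_content),
          file.path(out_dir, "pfm.tsv"))
      }
      logln("n60: %d reads scanned, %d retained, %d flank-fail, %d length-fail, %d duplicates",
            lib$n_reads_scanned, lib$n_retained, lib$n_flank_fail,
            lib$n_length_fail, lib$n_duplicates)
    } else if (st == "variants") {
      ref <- read_fasta(config$ref_fasta)
      pileup_paths <- strsplit(config$pileups, ",")[[1]]
      calls <- lapply(seq_along(pileup_paths), function(k) {
        cl <- call_variant_frequencies(read_pileup(pileup_paths[k]), ref[1],
                                       min_var_freq = num("min_var_freq", 0.001),
                                       error_rate = num("error_rate", 0.001))
        write_tsv_provenance(cl, file.path(out_dir, sprintf("variants_%d.tsv", k)))
        cl
      })
      hits <- intersect_enriched_variants(calls, alpha = num("alpha", 0.05))
      write_tsv_provenance(hits, file.path(out_dir, "variants_intersect.tsv"))
      logln("variants: %d samples, %d intersected enriched variants",
            length(calls), nrow(hits))
    }
  }
  invisible(out_dir)
}
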