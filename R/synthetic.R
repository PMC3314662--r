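#' Paired array design
#'
#' Builds the array-to-sample layout of the paired uterine-horn experiment:
#' each animal contributes exactly two arrays, one per uterine horn, the
#' inseminated (embryo-containing) and the non-inseminated (oocyte-containing)
#' side. The default study size is three animals, i.e. six arrays.
#'
#' @param n_animals Number of animals (>= 2).
#' @return A data frame with columns `array_id`, `animal_id`, `condition`
#'   (factor with levels `non_inseminated`, `inseminated`); one row per array.
#' @export
array_design <- function(n_animals = 3) {
  if (n_animals < 2) stop("n_animals must be >= 2")
  animal <- rep(sprintf("animal%d", seq_len(n_animals)), each = 2)
  cond <- rep(c("non_inseminated", "inseminated"), times = n_animals)
  data.frame(
    array_id = sprintf("%s_%s", animal, substr(cond, 1, 3)),
    animal_id = animal,
    condition = factor(cond, levels = c("non_inseminated", "inseminated")),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic paired-design expression data set
#'
#' Collects the parameters of the synthetic probe-level intensity generator.
#' Intensities are generated on the log2 scale as
#' `baseline(probe) + animal effect + array effect +
#' planted effect * [inseminated] + noise` and exponentiated, i.e. a
#' log-normal intensity model with additive Gaussian components on the log2
#' scale (the standard microarray noise assumption). Planted effects are log2
#' fold changes of the inseminated relative to the non-inseminated horn,
#' applied to every probe of the named gene.
#'
#' @param n_probes Number of probe sets (default 2000; the full-chip scale of
#'   ~24,000 is supported but not the test default).
#' @param n_animals Number of animals, each with one array per condition.
#' @param baseline_mean Mean log2 intensity of the probe baselines.
#' @param probe_sd SD of probe-specific baseline offsets (log2 units); probes
#'   differ strongly in affinity on real arrays.
#' @param animal_sd SD of the animal random effect (log2 units).
#' @param array_sd SD of the array random effect (log2 units); this is the
#'   random term of the per-probe-set mixed model.
#' @param noise_sd SD of the residual noise (log2 units); must be >= 0 (zero
#'   gives the deterministic limit used for exactness checks).
#' @param planted_effects Named numeric vector, gene symbol -> log2 fold
#'   change (inseminated vs non-inseminated). Genes absent from the
#'   annotation are ignored.
#' @param seed Integer seed; fully determines the generated table.
#' @return An object of class `sim_spec` (a list of the above).
#' @export
simulation_spec <- function(n_probes = 2000, n_animals = 3,
                            baseline_mean = 8, probe_sd = 0.5,
                            animal_sd = 0.2, array_sd = 0.1,
                            noise_sd = 0.25,
                            planted_effects = numeric(0), seed = 1L) {
  if (n_animals < 2) stop("invalid spec: n_animals must be >= 2")
  if (noise_sd < 0) stop("invalid spec: noise_sd must be >= 0")
  if (n_probes < 1) stop("invalid spec: n_probes must be >= 1")
  if (length(planted_effects) && is.null(names(planted_effects)))
    stop("invalid spec: planted_effects must be a named vector")
  structure(list(
    n_probes = as.integer(n_probes), n_animals = as.integer(n_animals),
    baseline_mean = baseline_mean, probe_sd = probe_sd,
    animal_sd = animal_sd, array_sd = array_sd, noise_sd = noise_sd,
    planted_effects = planted_effects, seed = as.integer(seed)
  ), class = "sim_spec")
}

#' Probe annotation for a synthetic chip
#'
#' Assigns probe identifiers to gene symbols, giving each of the supplied
#' pathway genes `probes_per_gene` probes (real chips carry several probe
#' sets per gene; MAL has two) and leaving the remaining probes unannotated
#' background, as on a genome-wide array where most probe sets do not map to
#' the pathway under study.
#'
#' @param n_probes Total number of probes.
#' @param pathway_genes Character vector of gene symbols to annotate.
#' @param probes_per_gene Probes assigned to each pathway gene.
#' @return A data frame with columns `probe_id`, `gene_symbol` (NA for
#'   background probes), `pathway_species` (here equal to `gene_symbol`).
#' @export
make_annotation <- function(n_probes, pathway_genes = character(0),
                            probes_per_gene = 2) {
  n_mapped <- length(pathway_genes) * probes_per_gene
  if (n_mapped > n_probes)
    stop("n_probes too small for the requested pathway annotation")
  gene <- c(rep(pathway_genes, each = probes_per_gene),
            rep(NA_character_, n_probes - n_mapped))
  data.frame(
    probe_id = sprintf("probe%05d_at", seq_len(n_probes)),
    gene_symbol = gene,
    pathway_species = gene,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic probe-level intensity table
#'
#' Draws a paired-design probe-by-array intensity matrix under the log-normal
#' model described in [simulation_spec()]. The same seed reproduces the table
#' bit for bit.
#'
#' @param spec A [simulation_spec()].
#' @param annotation A probe annotation data frame as from [make_annotation()]
#'   with at least `probe_id` and `gene_symbol`; its row count must equal
#'   `spec$n_probes`.
#' @return An object of class `probe_table`: a list with `probe_ids`,
#'   `array_ids`, `values` (raw-scale intensity matrix, probes x arrays),
#'   `design` (the [array_design()] data frame), and `log2` (FALSE; the
#'   matrix is on the raw intensity scale).
#' @export
#' @examples
#' spec <- simulation_spec(n_probes = 10, noise_sd = 0,
#'                         probe_sd = 0, animal_sd = 0, array_sd = 0,
#'                         planted_effects = c(GENE1 = -1), seed = 42)
#' ann <- make_annotation(10, "GENE1")
#' tab <- generate_intensities(spec, ann)
#' # every probe of GENE1 has inseminated/non-inseminated ratio 0.5
#' tab$values[1, "animal1_ins"] / tab$values[1, "animal1_non"]
generate_intensities <- function(spec, annotation) {
  stopifnot(inherits(spec, "sim_spec"))
  if (nrow(annotation) != spec$n_probes)
    stop("annotation must cover all probe ids: ",
         nrow(annotation), " rows for ", spec$n_probes, " probes")
  design <- array_design(spec$n_animals)
  n_arrays <- nrow(design)

  set.seed(spec$seed)
  probe_base <- spec$baseline_mean +
    stats::rnorm(spec$n_probes, 0, spec$probe_sd)
  animal_eff <- stats::rnorm(spec$n_animals, 0, spec$animal_sd)
  names(animal_eff) <- unique(design$animal_id)
  array_eff <- stats::rnorm(n_arrays, 0, spec$array_sd)

  fc <- rep(0, spec$n_probes)
  mapped <- !is.na(annotation$gene_symbol) &
    annotation$gene_symbol %in% names(spec$planted_effects)
  fc[mapped] <- spec$planted_effects[annotation$gene_symbol[mapped]]

  ins <- as.numeric(design$condition == "inseminated")
  log2mat <- outer(probe_base, rep(1, n_arrays)) +
    outer(rep(1, spec$n_probes), animal_eff[design$animal_id] + array_eff) +
    outer(fc, ins) +
    matrix(stats::rnorm(spec$n_probes * n_arrays, 0, spec$noise_sd),
           spec$n_probes, n_arrays)
  values <- 2^log2mat
  dimnames(values) <- list(annotation$probe_id, design$array_id)

  structure(list(
    probe_ids = annotation$probe_id, array_ids = design$array_id,
    values = values, design = design, log2 = FALSE
  ), class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes x %d arrays (%d animals), %s scale\n",
              length(x$probe_ids), length(x$array_ids),
              length(unique(x$design$animal_id)),
              if (isTRUE(x$log2)) "log2" else "raw"))
  invisible(x)
}

#' Per-probe condition ratios within animals
#'
#' For every probe and animal, the ratio of the inseminated to the
#' non-inseminated intensity — the quantity summarized per species for
#' scenario construction.
#'
#' @param table A `probe_table` on the raw intensity scale.
#' @return A matrix (probes x animals) of inseminated/non-inseminated ratios.
#' @export
probe_ratios <- function(table) {
  stopifnot(inherits(table, "probe_table"))
  v <- if (isTRUE(table$log2)) 2^table$values else table$values
  d <- table$design
  animals <- unique(d$animal_id)
  out <- sapply(animals, function(a) {
    ins <- d$array_id[d$animal_id == a & d$condition == "inseminated"]
    non <- d$array_id[d$animal_id == a & d$condition == "non_inseminated"]
    v[, ins] / v[, non]
  })
  dimnames(out) <- list(table$probe_ids, animals)
  out
}

#' Write / read a probe intensity table as TSV
#'
#' The on-disk form is two plain TSV files: a values table (`probe_id` plus
#' one column per array) and a design table (`array_id`, `animal_id`,
#' `condition`).
#'
#' @param table A `probe_table`.
#' @param values_path,design_path File paths for the two TSVs.
#' @return `write_probe_table` returns the paths invisibly;
#'   `read_probe_table` returns a `probe_table`.
#' @export
write_probe_table <- function(table, values_path, design_path) {
  stopifnot(inherits(table, "probe_table"))
  df <- data.frame(probe_id = table$probe_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values = values_path, design = design_path))
}

#' @rdname write_probe_table
#' @param log2 Whether the stored values are on the log2 scale.
#' @export
read_probe_table <- function(values_path, design_path, log2 = FALSE) {
  for (p in c(values_path, design_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  design$condition <- factor(design$condition,
                             levels = c("non_inseminated", "inseminated"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  if (!identical(colnames(values), design$array_id))
    stop("value columns do not match design array_ids")
  structure(list(
    probe_ids = df$probe_id, array_ids = design$array_id,
    values = values, design = design, log2 = log2
  ), class = "probe_table")
}
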