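# Configuration parsing (command-line flags and YAML config files),
# structured trace/summary output, and named presets for the headline
# parameter sets.

#' Named preset configurations
#'
#' Ready-made [run_config()] objects for the model's headline parameter
#' sets. Available presets:
#' \describe{
#'   \item{linked_default}{Linked loci, n = 20, mu = 1e-7, c_h = 0.2,
#'     concave fitness: the basic fixation run.}
#'   \item{linked_fast}{Linked loci at mu = 1e-4 (faster spread; the
#'     setting used for the trajectory figures).}
#'   \item{recombination_uniparental}{Recombination (P_r = 0.5) with
#'     dominant-U transmission in U x U matings, concave fitness.}
#'   \item{recombination_biparental_linear}{Recombination with biparental
#'     U x U matings under linear fitness (UPI climbs to its 0.5 ceiling).}
#'   \item{no_mating_types_concave}{No mating types, biparental U x U,
#'     concave fitness: polymorphic equilibrium.}
#'   \item{no_mating_types_uniparental}{No mating types with uniparental
#'     U x U matings (UU fixes).}
#'   \item{mitosis_stable_bpi}{n = 4 with 100 mitotic divisions before
#'     selection: vegetative segregation resolves heteroplasmy completely
#'     before selection acts, so biparental inheritance is stable.}
#' }
#'
#' @param name Preset name.
#' @return A [run_config()].
#' @export
preset_config <- function(name) {
  switch(name,
    linked_default = run_config(
      n = 20, mu = 1e-7, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_linked()),
    linked_fast = run_config(
      n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_linked()),
    recombination_uniparental = run_config(
      n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_recombination(P_r = 0.5, "uniparental")),
    recombination_biparental_linear = run_config(
      n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "linear"),
      scenario = scenario_recombination(P_r = 0.5, "biparental")),
    no_mating_types_concave = run_config(
      n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_no_mating_types("biparental")),
    no_mating_types_uniparental = run_config(
      n = 20, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_no_mating_types("uniparental")),
    mitosis_stable_bpi = run_config(
      n = 4, mu = 1e-4, fitness = fitness_spec(0.2, "concave"),
      scenario = scenario_mitosis(100, "before_selection")),
    stop("unknown preset: ", name, call. = FALSE))
}

#' Build a run configuration from flag-style arguments
#'
#' Accepts a named list of options as produced by a command-line parser or
#' read from a YAML config file (keys mirror the CLI flags with underscores
#' for dashes) and validates it into a [run_config()]. Unset keys take the
#' documented defaults; \code{mu_back} defaults to \code{mu} (neutral),
#' \code{mu/100} (deleterious) or \code{100*mu} (advantageous).
#'
#' @param opts Named list. Recognised keys: \code{preset}, \code{scenario}
#'   (\code{linked}, \code{recombination}, \code{no_mating_types},
#'   \code{mitosis}, \code{physarum}, \code{didymium}), \code{n},
#'   \code{mu}, \code{mu_back}, \code{cost}, \code{fitness},
#'   \code{direction}, \code{s}, \code{acc_fitness}, \code{p_r},
#'   \code{uu_regime}, \code{p_b}, \code{p_u1}, \code{p_u2},
#'   \code{divisions}, \code{mitosis_timing} (\code{before} or
#'   \code{midway}), \code{intro_freq}, \code{intro_placement},
#'   \code{eq_tol}, \code{max_generations}, \code{trace_every}.
#' @param config_file Optional YAML file whose keys are merged underneath
#'   \code{opts} (explicit options win).
#' @return A [run_config()].
#' @export
#' @examples
#' parse_config(list(scenario = "linked", n = 20, mu = 1e-7, cost = 0.2,
#'                   fitness = "concave"))
parse_config <- function(opts = list(), config_file = NULL) {
  if (!is.null(config_file)) {
    file_opts <- yaml::read_yaml(config_file)
    opts <- utils::modifyList(file_opts, opts[!vapply(opts, is.null,
                                                      logical(1))])
  }
  opts <- opts[!vapply(opts, is.null, logical(1))]
  if (!is.null(opts$preset)) return(preset_config(opts$preset))
  get <- function(key, default) if (!is.null(opts[[key]])) opts[[key]] else default

  fitness <- fitness_spec(
    c_h = get("cost", 0.2),
    shape = get("fitness", "concave"),
    direction = get("direction", "neutral"),
    s = get("s", 0),
    acc_shape = get("acc_fitness", "concave"))

  scen_name <- get("scenario", "linked")
  scen_name <- gsub("-", "_", scen_name)
  scenario <- switch(scen_name,
    linked = scenario_linked(),
    recombination = scenario_recombination(
      P_r = get("p_r", 0.5),
      uu_regime = get("uu_regime", "uniparental"),
      P_b = get("p_b", 0)),
    no_mating_types = scenario_no_mating_types(
      uu_regime = get("uu_regime", "uniparental"),
      P_b = get("p_b", 0)),
    mitosis = scenario_mitosis(
      divisions = get("divisions", 20),
      timing = switch(get("mitosis_timing", "before"),
                      before = "before_selection",
                      before_selection = "before_selection",
                      midway = "midway",
                      stop("invalid 'mitosis_timing'", call. = FALSE))),
    physarum = scenario_physarum(P_b = get("p_b", 0)),
    didymium = scenario_didymium(
      P_U1 = get("p_u1", 0.45), P_U2 = get("p_u2", 0.45),
      P_b = get("p_b", 0.1), P_r = get("p_r", 0.5)),
    stop("unknown scenario: ", scen_name, call. = FALSE))

  run_config(
    n = get("n", 20),
    mu = get("mu", 1e-4),
    mu_b = opts$mu_back,
    fitness = fitness,
    scenario = scenario,
    intro_freq = get("intro_freq", 1e-2),
    intro_placement = get("intro_placement", "homoplasmic_wild"),
    eq_tol = opts$eq_tol,
    max_generations = get("max_generations", 5e6),
    trace_every = get("trace_every", 10))
}

config_echo <- function(config) {
  sc <- config$scenario
  list(scenario = sc$name,
       scenario_params = sc$params,
       n = config$n, mu = config$mu, mu_back = config$mu_b,
       cost = config$fitness$c_h, fitness = config$fitness$shape,
       direction = config$fitness$direction, s = config$fitness$s,
       acc_fitness = config$fitness$acc_shape,
       divisions = sc$mitosis$divisions,
       mitosis_timing = sc$mitosis$timing,
       intro_freq = config$intro_freq,
       intro_placement = config$intro_placement,
       eq_tol = config$eq_tol,
       max_generations = config$max_generations,
       trace_every = config$trace_every)
}

#' Long-format trace of a completed run
#'
#' Per-generation allele and genotype frequencies, mean fitnesses and the
#' uniparental-transmission frequency; full gamete distributions are
#' included every \code{trace_every} generations. Generation 0 is the
#' introduction generation.
#'
#' @param run A [simulate_upi()] result.
#' @return A data frame with columns \code{generation}, \code{stage},
#'   \code{entity}, \code{count} (NA for aggregated rows) and
#'   \code{proportion}.
#' @export
run_trace <- function(run) {
  ngen <- nrow(run$allele_freq)
  gens <- seq_len(ngen)
  long <- function(mat, stage) {
    data.frame(generation = rep(gens, ncol(mat)),
               stage = stage,
               entity = rep(colnames(mat), each = ngen),
               count = NA_integer_,
               proportion = as.vector(mat))
  }
  snap_rows <- lapply(names(run$gamete_snapshots), function(g) {
    m <- run$gamete_snapshots[[g]]
    data.frame(generation = as.integer(g), stage = "gamete_distribution",
               entity = rep(rownames(m), ncol(m)),
               count = rep(as.integer(colnames(m)), each = nrow(m)),
               proportion = as.vector(m))
  })
  out <- rbind(long(run$allele_freq, "allele_freq"),
               long(run$genotype_freq, "genotype_freq"),
               long(run$mean_fitness, "mean_fitness"),
               long(run$gamete_fitness, "gamete_fitness"),
               data.frame(generation = gens, stage = "upi_freq",
                          entity = "upi", count = NA_integer_,
                          proportion = run$upi_freq),
               do.call(rbind, snap_rows))
  out[order(out$generation, out$stage, out$entity), , drop = FALSE]
}

#' Key-value summary of a completed run
#'
#' @param run A [simulate_upi()] result.
#' @return A list (convertible to JSON) with the generation counters,
#'   equilibrium frequencies, uniparental-transmission frequency, fixation
#'   flag, software version and a config echo sufficient to reproduce the
#'   run.
#' @export
run_summary <- function(run) {
  list(version = as.character(utils::packageVersion("upievol")),
       generations_burn_in = run$generations_burn_in,
       burn_in_converged = run$burn_in_converged,
       generations_to_final = run$generations_to_final,
       final_converged = run$final_converged,
       equilibrium_allele_freq = as.list(run$equilibrium_allele_freq),
       equilibrium_genotype_freq = as.list(run$equilibrium_genotype_freq),
       equilibrium_upi_freq = run$equilibrium_upi_freq,
       fixation = run$fixation,
       config = config_echo(run$config))
}

#' Write trace and summary files for a completed run
#'
#' @param run A [simulate_upi()] result.
#' @param out Output path prefix; writes \code{<out>_trace.csv} (or .json)
#'   and \code{<out>_summary.json}.
#' @param format \code{"csv"} or \code{"json"} for the trace table.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(run, out, format = c("csv", "json")) {
  format <- match.arg(format)
  trace <- run_trace(run)
  trace_path <- paste0(out, "_trace.", format)
  if (format == "csv") {
    utils::write.csv(trace, trace_path, row.names = FALSE)
  } else {
    jsonlite::write_json(trace, trace_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  summary_path <- paste0(out, "_summary.json")
  jsonlite::write_json(run_summary(run), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(trace = trace_path, summary = summary_path))
}
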