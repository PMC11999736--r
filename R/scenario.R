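#' Load a selection scenario from a YAML configuration file
#'
#' A scenario file describes a pool, a stringency schedule and run length in
#' YAML. Recognised top-level keys: `pool` (with `species`, a list of
#' `{label, A, k, p0}` records plus optional `class`/`leak` for
#' counter-selection pools; `Q`; `kback`), `artefact` (`Rart`, `p0`),
#' `schedule` (either `taus:` explicit list, or `tau0`/`decay`/`from_round`),
#' `schedule_counter` (same form, for counter-selection), `rounds`, `seed`,
#' `mutation` (`pben`, `pmin`, `u`, `lambda`, `ncyc`), `structure` (path to
#' a structure-constraint file, relative to the config). Unknown keys are an
#' error, listed by name. `Q` defaults to 0.2 and `kback` to 0.001.
#'
#' @param path Path to the YAML file.
#' @return An object of class `scenario_config`: the validated list, with
#'   `pool` turned into a [species_pool()] or [cofactor_pool()] and
#'   schedules expanded via [tau_schedule()].
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) abort("scenario file is empty; a `pool` block is required.")
  known <- c("pool", "artefact", "schedule", "schedule_counter", "rounds",
             "seed", "mutation", "structure", "name")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown scenario key(s): ", paste(extra, collapse = ", "), "."))
  }
  if (is.null(raw$pool)) abort("scenario file must contain a `pool` block.")
  if (is.null(raw$pool$species)) abort("`pool` must contain a `species` list.")
  species <- dplyr::bind_rows(lapply(raw$pool$species, as_tibble))
  Q <- raw$pool$Q %||% 0.2
  kback <- raw$pool$kback %||% 0.001
  rounds <- raw$rounds %||% 20L

  p_named <- sum(species$p0) + (raw$artefact$p0 %||% 0)
  if (p_named > 1) {
    abort(sprintf("species + artefact frequencies sum to %g > 1; cannot normalize.", p_named))
  }

  pool <- if ("class" %in% names(species)) {
    if (!is.null(raw$artefact)) abort("artefacts are not supported in counter-selection pools.")
    cofactor_pool(species, Q = Q, kback = kback)
  } else {
    species_pool(species, Q = Q, kback = kback, artefact = raw$artefact)
  }

  expand <- function(block) {
    if (is.null(block)) return(tau_schedule(n_rounds = rounds, decay = 1))
    if (!is.null(block$taus)) {
      tau_schedule(taus = as.numeric(unlist(block$taus)), n_rounds = rounds)
    } else {
      tau_schedule(tau0 = block$tau0 %||% 5, decay = block$decay %||% 5,
                   from_round = block$from_round %||% 6, n_rounds = rounds)
    }
  }

  mut <- if (!is.null(raw$mutation)) do.call(mutation_model, raw$mutation)
  struct <- if (!is.null(raw$structure)) {
    spath <- raw$structure
    if (!file.exists(spath)) spath <- file.path(dirname(path), raw$structure)
    if (!file.exists(spath)) abort(sprintf("structure file '%s' not found.", raw$structure))
    read_structure(spath)
  }

  structure(
    list(name = raw$name, pool = pool,
         schedule = expand(raw$schedule),
         schedule_counter = expand(raw$schedule_counter %||% raw$schedule),
         rounds = rounds, seed = raw$seed %||% 1L,
         mutation = mut, structure = struct),
    class = "scenario_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a trajectory as tab-separated values
#'
#' One row per (round, species), columns `round`, `tau`, `species`,
#' `frequency`, `enrichment`, written at full (17 significant digit)
#' precision so files round-trip losslessly. Lines starting with `#` carry
#' provenance (package version, and any `comments` supplied) and are
#' skipped on read.
#'
#' @param trajectory A `selex_trajectory`.
#' @param path Output file.
#' @param comments Optional character vector of extra `#` header lines.
#' @return [write_trajectory()] returns `path` invisibly;
#'   [read_trajectory()] returns a `selex_trajectory` (without the pool
#'   object, which a TSV does not carry).
#' @export
write_trajectory <- function(trajectory, path, comments = character()) {
  stopifnot(inherits(trajectory, "selex_trajectory"))
  hdr <- c(sprintf("# selexdyn %s trajectory, package version %s",
                   trajectory$kind, as.character(utils::packageVersion("selexdyn"))),
           paste0("# ", comments))
  hdr <- hdr[nzchar(sub("^# ?", "", hdr)) | seq_along(hdr) == 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tbl <- trajectory$frequencies
  writeLines(paste(names(tbl), collapse = "\t"), con)
  lines <- sprintf("%d\t%s\t%s\t%s\t%s",
                   tbl$round,
                   formatC(tbl$tau, digits = 17, format = "g"),
                   tbl$species,
                   formatC(tbl$frequency, digits = 17, format = "g"),
                   formatC(tbl$enrichment, digits = 17, format = "g"))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = c("NA", "nan"))
  tbl <- as_tibble(tbl)
  tbl$round <- as.integer(tbl$round)
  rounds <- sort(unique(tbl$round[tbl$round > 0]))
  taus <- tbl$tau[match(rounds, tbl$round)]
  new_trajectory(tbl, pool = NULL, taus = taus, kind = "restored")
}

#' Write the worked-example fixture files
#'
#' Deterministically writes the fixture set used throughout the package's
#' tests and examples into `dir`: the four-catalyst example pool as a
#' scenario YAML, structure-constraint files with the published constraint
#' counts of three well-studied ribozyme motifs (hammerhead-like: Lstr 39,
#' s 13, b 8, M 3; twister-like: Lstr 54, s 11, b 17, M 3;
#' 5'-anchored triphosphorylation-like: Lstr 44, s 13, b 11, M 2), and two
#' toy structures small enough for exhaustive enumeration. Positions within
#' the motifs are synthetic — frequencies depend only on the counts — and
#' the files say so.
#'
#' @param dir Output directory (created if needed).
#' @param seed Unused by the fixture content (which is deterministic);
#'   recorded in the scenario file.
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()

  scen <- file.path(dir, "example-pool.yaml")
  writeLines(c(
    "# four-catalyst example pool (synthetic)",
    "name: example-pool",
    "pool:",
    "  Q: 0.2",
    "  kback: 0.001",
    "  species:",
    "    - {label: seq1, A: 0.55, k: 1.0, p0: 1.0e-14}",
    "    - {label: seq2, A: 0.5,  k: 0.8, p0: 1.0e-14}",
    "    - {label: seq3, A: 0.7,  k: 0.6, p0: 1.0e-14}",
    "    - {label: seq4, A: 0.5,  k: 0.5, p0: 1.0e-14}",
    "schedule: {tau0: 5, decay: 5, from_round: 6}",
    "rounds: 20",
    sprintf("seed: %d", as.integer(seed))
  ), scen)
  files["scenario"] <- scen

  for (nm in c("hammerhead-like", "twister-like", "triphosphorylation-like",
               "toy-hairpin", "toy-two-module")) {
    f <- file.path(dir, paste0(nm, ".structure"))
    write_structure(fixture_structure(nm), f)
    files[nm] <- f
  }
  files
}

#' Built-in structure fixtures
#'
#' Returns one of the synthetic structure constraints shipped with the
#' package. The three ribozyme-like fixtures reproduce the published
#' constraint counts (`Lstr`, `s`, `b`, `M`, anchoring) of the hammerhead,
#' twister and triphosphorylation motifs; conserved/paired *positions* are
#' synthetic, since every frequency computed here depends only on the
#' counts. The toys are small enough for exhaustive enumeration.
#'
#' @param name One of `"hammerhead-like"`, `"twister-like"`,
#'   `"triphosphorylation-like"`, `"toy-hairpin"` (Lstr 4, s 1, b 1),
#'   `"toy-two-module"` (Lstr 6, s 2, b 1, M 2).
#' @return A [structure_constraint()].
#' @export
fixture_structure <- function(name = c("hammerhead-like", "twister-like",
                                       "triphosphorylation-like",
                                       "toy-hairpin", "toy-two-module")) {
  name <- match.arg(name)
  rep_bases <- function(pos) {
    setNames(rep(c("C", "U", "G", "A"), length.out = length(pos)), pos)
  }
  switch(name,
    "hammerhead-like" = structure_constraint(
      39,
      conserved = rep_bases(c(4:8, 17:20, 29:32)),
      pairs = rbind(c(1, 12), c(2, 11), c(3, 10),
                    c(14, 26), c(15, 25), c(16, 24),
                    c(27, 39), c(28, 38)),
      breaks = c(13, 26), name = name
    ),
    "twister-like" = structure_constraint(
      54,
      conserved = rep_bases(c(8:12, 26:31)),
      pairs = rbind(c(1, 18), c(2, 17), c(3, 16), c(4, 15), c(5, 14),
                    c(6, 13), c(7, 36),
                    c(19, 35), c(20, 34), c(21, 33), c(22, 32),
                    c(37, 54), c(38, 53), c(39, 52), c(40, 51),
                    c(41, 50), c(42, 49)),
      breaks = c(18, 36), name = name
    ),
    "triphosphorylation-like" = structure_constraint(
      44,
      conserved = rep_bases(c(5:11, 25:30)),
      pairs = rbind(c(1, 22), c(2, 21), c(3, 20), c(4, 19),
                    c(12, 18), c(13, 17),
                    c(23, 44), c(24, 43), c(31, 42), c(32, 41), c(33, 40)),
      breaks = 22, anchored5 = TRUE, name = name
    ),
    "toy-hairpin" = structure_constraint(
      4, conserved = c(`1` = "G"), pairs = rbind(c(2, 4)), name = name
    ),
    "toy-two-module" = structure_constraint(
      6, conserved = c(`1` = "G", `5` = "A"), pairs = rbind(c(2, 4)),
      breaks = 4, name = name
    )
  )
}
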