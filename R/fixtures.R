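#' Named, versioned example datasets with known truth
#'
#' Small bundled scenarios used for documentation and validation; each is
#' generated in code (no stored data) and carries the quantities it was
#' designed to reproduce.
#'
#' * `"toy-3-subjects"` -- an illness-death model (healthy, ill, dead) with
#'   three hand-traceable subjects; the expected counting-process episode
#'   table and Nelson-Aalen tables, derived by hand, are included.
#' * `"illness-death-500"` -- 500 simulated subjects with constant
#'   intensities (0.1 healthy->ill, 0.05 healthy->dead, 0.2 ill->dead), one
#'   binary covariate `sev` (prevalence 0.5) acting on healthy->ill with
#'   log hazard ratio `log(2)`, administrative censoring at day 30.
#' * `"seven-state-divine-like"` -- a synthetic hospital-course cohort
#'   shaped like a COVID-19 ward model: 7 states (two initial admission
#'   severities, three transient care levels, discharge and death
#'   absorbing), 14 transitions of which the four `* -> death` transitions
#'   out of non-critical states are rare, covariates `age` and `sex`; 400
#'   subjects, administrative censoring at day 60.
#'
#' Regenerating a fixture always reproduces it bit-identically (fixed
#' internal seed).
#'
#' @param name one of the fixture names above.
#' @return A list with elements `name`, `graph`, `subjects`, and
#'   `expected` (a list of stored truths: episode tables, Nelson-Aalen
#'   tables, simulation parameters, as appropriate).
#' @export
make_fixture <- function(name = c("toy-3-subjects", "illness-death-500",
                                  "seven-state-divine-like")) {
  name <- match.arg(name)
  switch(name,
         "toy-3-subjects" = fixture_toy3(),
         "illness-death-500" = fixture_id500(),
         "seven-state-divine-like" = fixture_divine())
}

illness_death_graph <- function() {
  msm_graph(c("healthy", "ill", "dead"),
            list(c("healthy", "ill"), c("healthy", "dead"),
                 c("ill", "dead")))
}

fixture_toy3 <- function() {
  graph <- illness_death_graph()
  subjects <- data.frame(
    id = 1:3,
    start_state = "healthy",
    ill_time = c(3, 5, 4), ill_status = c(1L, 0L, 0L),
    dead_time = c(10, 5, 4), dead_status = c(1L, 0L, 1L),
    age = c(60, 50, 70),
    stringsAsFactors = FALSE)
  # hand-derived expansion: subject 1 healthy(0) -> ill(3) -> dead(10),
  # subject 2 censored in healthy at 5, subject 3 healthy(0) -> dead(4)
  episodes <- data.frame(
    id = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    from = c("healthy", "healthy", "ill", "healthy", "healthy",
             "healthy", "healthy"),
    to = c("ill", "dead", "dead", "ill", "dead", "ill", "dead"),
    trans = c("healthy->ill", "healthy->dead", "ill->dead",
              "healthy->ill", "healthy->dead",
              "healthy->ill", "healthy->dead"),
    tstart = c(0, 0, 3, 0, 0, 0, 0),
    tstop = c(3, 3, 10, 5, 5, 4, 4),
    status = c(1L, 0L, 1L, 0L, 0L, 0L, 1L),
    age = c(60, 60, 60, 50, 50, 70, 70),
    stringsAsFactors = FALSE)
  # hand-derived Nelson-Aalen: healthy->ill jumps at 3 with Y=3 (all three
  # in healthy just before 3); healthy->dead at 4 with Y=2 (subjects 2, 3);
  # ill->dead at 10 with Y=1
  nelson_aalen <- list(
    "healthy->ill" = data.frame(time = 3, nevent = 1L, nrisk = 3,
                                dhaz = 1 / 3, cumhaz = 1 / 3),
    "healthy->dead" = data.frame(time = 4, nevent = 1L, nrisk = 2,
                                 dhaz = 1 / 2, cumhaz = 1 / 2),
    "ill->dead" = data.frame(time = 10, nevent = 1L, nrisk = 1,
                             dhaz = 1, cumhaz = 1))
  list(name = "toy-3-subjects", graph = graph, subjects = subjects,
       expected = list(episodes = episodes, nelson_aalen = nelson_aalen))
}

fixture_id500 <- function() {
  graph <- illness_death_graph()
  rates <- c("healthy->ill" = 0.1, "healthy->dead" = 0.05,
             "ill->dead" = 0.2)
  beta <- log(2)
  spec <- msm_sim_spec(
    graph,
    hazards = lapply(rates, function(r) list(dist = "constant", rate = r)),
    effects = list("healthy->ill" = c(sev = beta)),
    covariates = list(sev = list(type = "binary", p = 0.5)),
    init = c(healthy = 1),
    cens_time = 30)
  subjects <- simulate_paths(spec, n = 500, seed = 20230524)
  list(name = "illness-death-500", graph = graph, subjects = subjects,
       expected = list(rates = rates, beta = c("healthy->ill.sev" = beta),
                       seed = 20230524, spec = spec))
}

divine_like_graph <- function() {
  msm_graph(
    c("nopneum", "pneum", "nimv", "imv", "reco", "dcharg", "death"),
    c("nopneum->reco", "nopneum->nimv", "nopneum->dcharg", "nopneum->death",
      "pneum->reco", "pneum->nimv", "pneum->imv", "pneum->death",
      "nimv->imv", "nimv->death",
      "imv->reco", "imv->death",
      "reco->dcharg", "reco->death"))
}

fixture_divine <- function() {
  graph <- divine_like_graph()
  # day^-1 exit rates: ward patients leave within days, invasive
  # ventilation has a ~14-day median total stay, and death from
  # non-critical states is rare
  rates <- c("nopneum->reco" = 0.12, "nopneum->nimv" = 0.03,
             "nopneum->dcharg" = 0.10, "nopneum->death" = 0.002,
             "pneum->reco" = 0.08, "pneum->nimv" = 0.05,
             "pneum->imv" = 0.04, "pneum->death" = 0.003,
             "nimv->imv" = 0.06, "nimv->death" = 0.004,
             "imv->reco" = 0.035, "imv->death" = 0.015,
             "reco->dcharg" = 0.30, "reco->death" = 0.002)
  spec <- msm_sim_spec(
    graph,
    hazards = lapply(rates, function(r) list(dist = "constant", rate = r)),
    effects = list("imv->death" = c(age = 0.03),
                   "nopneum->dcharg" = c(sex = -0.2)),
    covariates = list(age = list(type = "normal", mean = 60, sd = 15),
                      sex = list(type = "binary", p = 0.5,
                                 labels = c("Man", "Woman"))),
    init = c(nopneum = 0.7, pneum = 0.3),
    cens_time = 60)
  subjects <- simulate_paths(spec, n = 400, seed = 7107)
  list(name = "seven-state-divine-like", graph = graph, subjects = subjects,
       expected = list(rates = rates, seed = 7107, spec = spec,
                       n_initial = 2L, n_transient = 3L, n_absorbing = 2L))
}
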