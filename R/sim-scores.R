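#' Configuration for the ordinal score generator
#'
#' Emulates blinded clinical / histopathology grading of injured corneas:
#' each eye receives one ordinal grade (1-5) per parameter, drawn from a
#' per-group probability vector over the grades.
#'
#' @param n_ctr Number of control (vehicle-treated) eyes, default 4.
#' @param n_aca Number of antibody-treated eyes, default 6.
#' @param parameters Character vector of graded parameters; default the six
#'   study parameters (depth, opacity, edema, vascularization from in-life
#'   slit-lamp grading; fibrosis and inflammation from histopathology).
#' @param grade_probs Named list with elements `Ctr` and `ACA`, each either
#'   a length-5 probability vector shared by all parameters or a matrix
#'   with one row per parameter. Probabilities must sum to 1. Default: both
#'   groups uniform.
#' @param seed Integer RNG seed.
#' @return An object of class `score_sim_config`.
#' @export
score_sim_config <- function(n_ctr = 4, n_aca = 6,
                             parameters = c("depth", "opacity", "edema",
                                            "vascularization", "fibrosis",
                                            "inflammation"),
                             grade_probs = NULL, seed = 1) {
  if (n_ctr < 1 || n_aca < 1) stop("both groups need at least one eye")
  if (is.null(grade_probs)) {
    grade_probs <- list(Ctr = rep(0.2, 5), ACA = rep(0.2, 5))
  }
  for (g in c("Ctr", "ACA")) {
    p <- grade_probs[[g]]
    if (is.null(p)) stop("grade_probs needs elements 'Ctr' and 'ACA'")
    p <- if (is.matrix(p)) p else matrix(p, nrow = length(parameters),
                                         ncol = length(p), byrow = TRUE)
    if (ncol(p) != 5 || nrow(p) != length(parameters)) {
      stop("grade_probs entries must have 5 grade columns and one row per parameter")
    }
    if (any(abs(rowSums(p) - 1) > 1e-8)) {
      stop("grade probability vectors must sum to 1")
    }
    grade_probs[[g]] <- p
  }
  structure(list(n_ctr = as.integer(n_ctr), n_aca = as.integer(n_aca),
                 parameters = parameters, grade_probs = grade_probs,
                 seed = as.integer(seed)),
            class = "score_sim_config")
}

#' Generate an ordinal score table
#'
#' @param cfg A `score_sim_config`.
#' @return Data frame with columns `eye_id`, `group`, `parameter`, `grade`,
#'   reproducible under a fixed seed.
#' @export
generate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "score_sim_config"))
  set.seed(cfg$seed)
  eyes <- data.frame(
    eye_id = c(sprintf("CTR%02d", seq_len(cfg$n_ctr)),
               sprintf("ACA%02d", seq_len(cfg$n_aca))),
    group = c(rep("Ctr", cfg$n_ctr), rep("ACA", cfg$n_aca)))
  rows <- list()
  for (i in seq_len(nrow(eyes))) {
    probs <- cfg$grade_probs[[eyes$group[i]]]
    for (k in seq_along(cfg$parameters)) {
      rows[[length(rows) + 1]] <- data.frame(
        eye_id = eyes$eye_id[i], group = eyes$group[i],
        parameter = cfg$parameters[k],
        grade = sample.int(5, 1, prob = probs[k, ]))
    }
  }
  do.call(rbind, rows)
}

#' Write / read a score table CSV
#'
#' Columns `eye_id, group, parameter, grade`.
#'
#' @param scores Data frame from [generate_scores()].
#' @param path CSV path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("eye_id", "group", "parameter", "grade")
  if (!all(need %in% names(df))) {
    stop("score table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
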