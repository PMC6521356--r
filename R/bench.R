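# Self-contained benchmark generators and closed-form oracles. These are
# deliberately implemented apart from the estimator/integrator code paths
# they validate: the closed forms below come from pencil-and-paper variance
# algebra, not from the Saltelli machinery.

#' Analytic test function container
#'
#' @param name Label.
#' @param k Dimension.
#' @param evaluator Function mapping a unit-hypercube vector (length k) to a
#'   scalar.
#' @param closed_form_S1,closed_form_ST Known index vectors.
#' @return An `analytic_test_function`.
#' @export
analytic_test_function <- function(name, k, evaluator, closed_form_S1,
                                   closed_form_ST) {
  stopifnot(length(closed_form_S1) == k, length(closed_form_ST) == k,
            all(closed_form_S1 >= 0), all(closed_form_ST <= 1 + 1e-12),
            sum(closed_form_S1) <= 1 + 1e-12)
  structure(list(name = name, k = k, evaluator = evaluator,
                 closed_form_S1 = closed_form_S1,
                 closed_form_ST = closed_form_ST),
            class = "analytic_test_function")
}

#' Ishigami benchmark function
#'
#' `f(x) = sin(x1) + a sin^2(x2) + b x3^4 sin(x1)` with inputs uniform on
#' `[-pi, pi]^3` (the evaluator maps the unit cube onto that range). The
#' community-standard configuration `a = 7, b = 0.1` is the default. Closed
#' forms (independent variance algebra): with
#' `V = a^2/8 + b pi^4/5 + b^2 pi^8/18 + 1/2`,
#' `V1 = (1 + b pi^4/5)^2 / 2`, `V2 = a^2/8`, `V3 = 0`,
#' `VT3 = 8 b^2 pi^8 / 225`.
#'
#' @param a,b Ishigami constants.
#' @return An [analytic_test_function()] with `k = 3`.
#' @export
ishigami_function <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- pi^8 * b^2 * (1 / 18 - 1 / 50)  # = 8 b^2 pi^8 / 225
  V <- V1 + V2 + V13
  evaluator <- function(u) {
    x <- -pi + 2 * pi * u
    sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
  }
  analytic_test_function("ishigami", 3L, evaluator,
                         closed_form_S1 = c(V1, V2, 0) / V,
                         closed_form_ST = c(V1 + V13, V2, V13) / V)
}

#' Additive linear benchmark
#'
#' `Y = X1 + ... + Xk`, `Xi` iid uniform on `[0, 1]`. Purely additive, so
#' `S1_i = ST_i = 1/k` exactly and the first-order indices sum to one.
#'
#' @param k Dimension (>= 1).
#' @return An [analytic_test_function()].
#' @export
additive_linear <- function(k) {
  stopifnot(k >= 1)
  analytic_test_function(paste0("additive_linear_k", k), as.integer(k),
                         evaluator = function(u) sum(u),
                         closed_form_S1 = rep(1 / k, k),
                         closed_form_ST = rep(1 / k, k))
}

#' Unit parameter space for an analytic benchmark
#'
#' @param fn An [analytic_test_function()].
#' @return A [parameter_space()] of `k` linear entries on `[0, 1)`.
#' @export
unit_space <- function(fn) {
  parameter_space(paste0("x", seq_len(fn$k)), rep(0, fn$k),
                  rep(1, fn$k), "linear")
}

#' Sobol indices of an analytic benchmark via the Saltelli estimators
#'
#' @param fn An [analytic_test_function()].
#' @param N Base sample count.
#' @param skip Burn-in; default next power of two `>= N`.
#' @return A `sensitivity_result`.
#' @export
benchmark_gsa <- function(fn, N = 8192, skip = NULL) {
  design <- saltelli_design(unit_space(fn), N, skip = skip)
  bundle <- evaluate_design(design, fn$evaluator)
  analyze_bundle(bundle, output_name = fn$name)
}

#' Brute-force double-loop Monte Carlo Sobol indices
#'
#' Independent oracle for the Saltelli estimators: estimates
#' `V(E(Y|Xi))/V(Y)` by an explicit nested loop (outer over values of `Xi`,
#' inner averaging over the complement), and the total effect from
#' `E(V(Y|X~i))/V(Y)` with the roles reversed. Shares no code with the
#' product-form estimators. Practical only for small `k` and modest sample
#' counts.
#'
#' @param fn An [analytic_test_function()].
#' @param n_outer,n_inner Loop sizes. The oracle's own Monte Carlo error
#'   scales as the conditional-variance spread over `sqrt(n_outer)`; the
#'   defaults keep it a few times smaller than the 0.02-0.03 bands the
#'   Saltelli estimates are checked against.
#' @param seed RNG seed.
#' @return List with `S1` and `ST` vectors.
#' @export
double_loop_indices <- function(fn, n_outer = 2048, n_inner = 512, seed = 1) {
  k <- fn$k
  withr::with_seed(seed, {
    total <- matrix(stats::runif(65536 * k), ncol = k)
    VY <- stats::var(apply(total, 1, fn$evaluator))
    S1 <- ST <- numeric(k)
    for (i in seq_len(k)) {
      # outer draws are stratified (one per equal slab) so the outer-loop
      # averaging error decays faster than plain Monte Carlo
      xi <- (sample(n_outer) - stats::runif(n_outer)) / n_outer
      cond_mean <- vapply(xi, function(v) {
        u <- matrix(stats::runif(n_inner * k), ncol = k)
        u[, i] <- v
        mean(apply(u, 1, fn$evaluator))
      }, 0.0)
      S1[i] <- stats::var(cond_mean) / VY
      base <- lhs::randomLHS(n_outer, k)
      cond_var <- vapply(seq_len(n_outer), function(j) {
        u <- base[rep(j, n_inner), , drop = FALSE]
        u[, i] <- stats::runif(n_inner)
        stats::var(apply(u, 1, fn$evaluator))
      }, 0.0)
      ST[i] <- mean(cond_var) / VY
    }
    list(S1 = S1, ST = ST)
  })
}

#' Toy two-step decay network with closed-form solution
#'
#' `A -> B` (rate k1), `B -> 0` (rate k2), single compartment. The closed
#' forms `A(t) = A0 exp(-k1 t)` and
#' `B(t) = A0 k1 (exp(-k1 t) - exp(-k2 t)) / (k2 - k1)` (with the limit
#' `A0 k1 t exp(-k1 t)` at `k1 = k2`) serve as the integrator oracle.
#'
#' @param k1,k2 Rate constants (1/h).
#' @param A0 Initial amount of A (nM).
#' @return List with `net` (a `reaction_network`, including an inert NRG
#'   species so the simulation interface applies) and `closed_form(t)`
#'   returning a data.frame with columns `A`, `B`.
#' @export
toy_decay_network <- function(k1 = 1, k2 = 2, A0 = 1) {
  compartments <- data.frame(id = "cytoplasm", name = "Cytoplasm", volume = 1,
                             stringsAsFactors = FALSE)
  species <- data.frame(id = c("NRG", "A", "B"),
                        name = c("inert ligand", "A", "B"),
                        compartment = "cytoplasm",
                        initial_amount = c(0, A0, 0),
                        role = c("ligand", "protein", "protein"),
                        stringsAsFactors = FALSE)
  reactions <- list(
    reaction("D1", "A decay to B", c(A = 1), c(B = 1),
             rate_law("mass_action_irreversible", c(kf = "k1"))),
    reaction("D2", "B degradation", c(B = 1), rate_law =
             rate_law("mass_action_irreversible", c(kf = "k2"))))
  net <- new_network(compartments, species, reactions,
                     parameters = c(k1 = k1, k2 = k2),
                     flags = list(heterodimerization_on = FALSE,
                                  jak_independent_on = FALSE))
  closed_form <- function(t) {
    A <- A0 * exp(-k1 * t)
    B <- if (isTRUE(all.equal(k1, k2))) A0 * k1 * t * exp(-k1 * t)
         else A0 * k1 * (exp(-k1 * t) - exp(-k2 * t)) / (k2 - k1)
    data.frame(t = t, A = A, B = B)
  }
  list(net = net, closed_form = closed_form)
}

#' Generate a pseudo-experimental fold-change table
#'
#' Emulates an RT-PCR readout of beta-casein expression across NRG doses and
#' the three time windows (0-12, 12-24, 24-48 h): model interval integrals
#' are normalized to the zero-NRG (HC-only) control and multiplied by
#' lognormal noise (multiplicative and positive, matching fold-change
#' semantics). The control row is fixed at 1.
#'
#' @param readouts data.frame from [readout_table()] covering a dose series
#'   that includes dose 0 (the control).
#' @param noise_sigma Lognormal sigma (0 gives exact model fold changes).
#' @param seed Integer seed.
#' @return A `pseudo_experiment`: list with `doses`, `intervals`,
#'   `fold_change` (doses x intervals matrix), `noise_sigma`, `seed`.
#' @export
generate_pseudo_experiment <- function(readouts, noise_sigma = 0.1, seed = 1) {
  cols <- c("integral_0_12", "integral_12_24", "integral_24_48")
  if (!any(readouts$dose_nM == 0))
    stop("pseudo-experiment needs the zero-NRG control dose")
  readouts <- readouts[order(readouts$dose_nM), ]
  control <- as.numeric(readouts[readouts$dose_nM == 0, cols][1, ])
  fc <- sweep(as.matrix(readouts[, cols]), 2, control, "/")
  noise <- withr::with_seed(seed,
    matrix(exp(stats::rnorm(length(fc), 0, noise_sigma)), nrow = nrow(fc)))
  fc <- fc * noise
  fc[readouts$dose_nM == 0, ] <- 1  # control defines the unit fold change
  dimnames(fc) <- list(paste0("dose_", readouts$dose_nM), cols)
  structure(list(doses = readouts$dose_nM,
                 intervals = c("0-12", "12-24", "24-48"),
                 fold_change = fc, noise_sigma = noise_sigma, seed = seed),
            class = "pseudo_experiment")
}

#' Pseudo-experiment as a tidy fold-change table
#'
#' @param pe A `pseudo_experiment`.
#' @return data.frame with columns dose_nM, interval, fold_change.
#' @export
pseudo_experiment_table <- function(pe) {
  data.frame(dose_nM = rep(pe$doses, times = length(pe$intervals)),
             interval = rep(pe$intervals, each = length(pe$doses)),
             fold_change = as.vector(pe$fold_change), row.names = NULL)
}
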