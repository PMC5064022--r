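#' Build a Markov gating scheme
#'
#' A gating scheme is a labelled, directed state graph: each state carries
#' a conducting flag, each transition a voltage-dependent [rate_law()].
#' The master equation \eqn{dp/dt = p Q(V)} over the scheme's generator
#' matrix governs state-occupancy dynamics.
#'
#' @param states A data frame with columns `state` (unique character
#'   labels) and `conducting` (logical).
#' @param transitions A data frame with columns `label` (unique transition
#'   name), `from`, `to` (state labels, `from != to`), `amplitude` (s^-1,
#'   non-negative) and `charge` (effective valence).
#' @param constants A [phys_constants()] object.
#' @param name Optional scheme name, carried through metadata.
#'
#' @return An object of class `iks_scheme`: a list with elements `states`
#'   (tibble), `transitions` (tibble), `constants` and `name`.
#' @seealso [iks_scheme()] for the packaged IKs preset.
#' @export
gating_scheme <- function(states, transitions, constants = phys_constants(),
                          name = "scheme") {
  states <- tibble::as_tibble(states)
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("state", "conducting") %in% names(states)),
            all(c("label", "from", "to", "amplitude", "charge") %in%
                  names(transitions)))
  states <- states[c("state", "conducting")]
  transitions <- transitions[c("label", "from", "to", "amplitude", "charge")]
  scheme <- structure(
    list(states = states, transitions = transitions,
         constants = constants, name = name),
    class = "iks_scheme")
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  st <- scheme$states
  tr <- scheme$transitions
  if (anyDuplicated(st$state)) {
    abort("State labels must be unique.", class = "iksim_config_error")
  }
  if (!is.logical(st$conducting) || anyNA(st$conducting)) {
    abort("`conducting` must be logical without NA.",
          class = "iksim_config_error")
  }
  if (anyDuplicated(tr$label)) {
    abort("Transition labels must be unique.", class = "iksim_config_error")
  }
  if (any(tr$from == tr$to)) {
    abort("Transitions must connect distinct states.",
          class = "iksim_config_error")
  }
  unknown <- setdiff(c(tr$from, tr$to), st$state)
  if (length(unknown)) {
    abort(paste0("Transition references unknown state(s): ",
                 paste(unique(unknown), collapse = ", ")),
          class = "iksim_config_error")
  }
  if (anyDuplicated(paste(tr$from, tr$to))) {
    abort("Duplicate transition between the same ordered state pair.",
          class = "iksim_config_error")
  }
  if (any(!is.finite(tr$amplitude)) || any(tr$amplitude < 0) ||
      any(!is.finite(tr$charge))) {
    abort("Transition amplitudes must be non-negative and finite.",
          class = "iksim_config_error")
  }
  # weak connectivity of the state graph (edges taken as undirected;
  # zero-amplitude edges still count structurally)
  n <- nrow(st)
  idx <- stats::setNames(seq_len(n), st$state)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(tr))) {
    i <- idx[[tr$from[k]]]; j <- idx[[tr$to[k]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    for (j in adj[[i]]) if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
  }
  if (!all(seen)) {
    abort("State graph is not connected.", class = "iksim_config_error")
  }
  invisible(scheme)
}

#' @export
print.iks_scheme <- function(x, ...) {
  cond <- x$states$state[x$states$conducting]
  cat(sprintf("<iks_scheme> '%s': %d states (conducting: %s), %d transitions, T = %.2f K\n",
              x$name, nrow(x$states), paste(cond, collapse = ", "),
              nrow(x$transitions), x$constants$T))
  print(x$transitions, n = Inf)
  invisible(x)
}

#' Number of states in a scheme
#' @param scheme An `iks_scheme`.
#' @return Integer count of states.
#' @export
n_states <- function(scheme) nrow(scheme$states)

#' The packaged IKs (Kv7.1/KCNE1) gating scheme
#'
#' Six-state scheme for the slow delayed-rectifier current: three resting
#' closed states `C1`, `C2`, `C3`, two open states `O1`, `O2`, and a
#' stable ("inactivated") closed state `C2s` reached from `C2`.  Rates are
#' exponential functions of the reduced potential \eqn{\varphi = VF/RT}
#' (in s^-1):
#' \itemize{
#'  \item `C1 <-> C2`: `alpha1 = exp(0.47 phi)`, `beta1 = 0.2 exp(-0.35 phi)`
#'  \item `C2 <-> C3`: `alpha2 = 0.46 exp(0.47 phi)`, `beta2 = 3.3 exp(-0.35 phi)`
#'  \item `C3 <-> O1`: `alpha3 = 24 exp(0.06 phi)`, `beta3 = 19 exp(-0.007 phi)`
#'  \item `O1 <-> O2`: `epsilon = 4.6 exp(0.8 phi)`, `delta = 1.4 exp(-0.7 phi)`
#'  \item `C2 -> C2s`: `gamma = 10`; `C2s -> C2`: `rho`
#' }
#' The gating-modifier drug acts purely through `rho`, the exit rate from
#' the stabilized closed state: `rho = 10` s^-1 for drug-free channels and
#' `rho = 0.1` s^-1 (100-fold smaller) for drug-bound channels, which
#' traps depolarized channels in `C2s` and delays opening.
#'
#' @param drug `"free"` (default) or `"bound"`.
#' @param constants A [phys_constants()] object.
#'
#' @return An `iks_scheme`.
#' @examples
#' iks_scheme()
#' iks_scheme("bound")
#' @export
iks_scheme <- function(drug = c("free", "bound"), constants = phys_constants()) {
  drug <- match.arg(drug)
  states <- tibble::tibble(
    state = c("C1", "C2", "C3", "O1", "O2", "C2s"),
    conducting = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  transitions <- tibble::tribble(
    ~label,     ~from,  ~to,   ~amplitude, ~charge,
    "alpha1",   "C1",   "C2",   1,          0.47,
    "beta1",    "C2",   "C1",   0.2,       -0.35,
    "alpha2",   "C2",   "C3",   0.46,       0.47,
    "beta2",    "C3",   "C2",   3.3,       -0.35,
    "alpha3",   "C3",   "O1",  24,          0.06,
    "beta3",    "O1",   "C3",  19,         -0.007,
    "epsilon",  "O1",   "O2",   4.6,        0.8,
    "delta",    "O2",   "O1",   1.4,       -0.7,
    "gamma",    "C2",   "C2s", 10,          0,
    "rho",      "C2s",  "C2",  10,          0)
  scheme <- gating_scheme(states, transitions, constants,
                          name = paste0("iks-", drug))
  if (drug == "bound") scheme <- apply_drug_config(scheme, ac1_bound_config())
  scheme
}

#' Drug configurations: named rate-law overrides
#'
#' A drug configuration replaces the rate laws of named transitions,
#' leaving the rest of the scheme untouched.  The adamantane
#' gating-modifier presets override only `rho`, the `C2s -> C2` exit
#' rate: 10 s^-1 drug-free, 0.1 s^-1 drug-bound.
#'
#' @param ... Named arguments; each name is a transition label and each
#'   value a [rate_law()].
#' @return An object of class `iks_drug_config` (named list of rate laws).
#' @examples
#' ac1_bound_config()
#' apply_drug_config(iks_scheme(), ac1_bound_config())
#' @export
drug_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("All overrides must be named by transition label.",
          class = "iksim_config_error")
  }
  ok <- vapply(overrides, inherits, logical(1), what = "iks_rate_law")
  if (!all(ok)) {
    abort("Each override must be a `rate_law()`.",
          class = "iksim_config_error")
  }
  structure(overrides, class = "iks_drug_config")
}

#' @rdname drug_config
#' @export
ac1_bound_config <- function() drug_config(rho = rate_law(0.1, 0))

#' @rdname drug_config
#' @export
drug_free_config <- function() drug_config(rho = rate_law(10, 0))

#' Apply a drug configuration to a scheme
#'
#' Returns a new scheme with the overridden rate laws; the input scheme is
#' not modified.
#'
#' @param scheme An `iks_scheme`.
#' @param config An [drug_config()] object.
#' @return A new `iks_scheme`.
#' @export
apply_drug_config <- function(scheme, config) {
  stopifnot(inherits(scheme, "iks_scheme"), inherits(config, "iks_drug_config"))
  tr <- scheme$transitions
  for (lab in names(config)) {
    k <- which(tr$label == lab)
    if (!length(k)) {
      abort(paste0("Drug config names unknown transition '", lab, "'."),
            class = "iksim_config_error")
    }
    tr$amplitude[k] <- config[[lab]]$amplitude
    tr$charge[k] <- config[[lab]]$charge
  }
  out <- scheme
  out$transitions <- tr
  if (length(config)) out$name <- paste0(scheme$name, "+drug")
  validate_scheme(out)
  out
}

#' Ligand-binding specification for the explicit binding extension
#'
#' Describes mass-action drug binding: association rate `kon` (M^-1 s^-1)
#' times ligand concentration from every binding-competent state to its
#' drug-bound twin, and dissociation `koff` (s^-1) back.  The bound copy
#' of the scheme carries the bound drug configuration (by default the
#' 100-fold slowed `rho`).  The dissociation constant is
#' `Kd = koff / kon`.
#'
#' The two-configuration gating model by itself describes only fully
#' drug-free versus fully drug-bound channel populations; this extension
#' is what lets the package emulate wash-in time courses and
#' concentration-dependent occupancy.
#'
#' @param kon Association rate constant, M^-1 s^-1 (>= 0).
#' @param koff Dissociation rate constant, s^-1 (>= 0).
#' @param concentration_M Ligand concentration in mol/L (>= 0).
#' @param competent Character vector of binding-competent state labels
#'   (default: the closed states of the IKs scheme, reflecting
#'   closed-state drug access).
#' @param bound_config [drug_config()] applied to the bound copy.
#'
#' @return An object of class `iks_binding_spec`.
#' @export
binding_spec <- function(kon, koff, concentration_M,
                         competent = c("C1", "C2", "C3", "C2s"),
                         bound_config = ac1_bound_config()) {
  if (!is.numeric(kon) || kon < 0 || !is.numeric(koff) || koff < 0 ||
      !is.numeric(concentration_M) || concentration_M < 0) {
    abort("`kon`, `koff` and `concentration_M` must be non-negative.",
          class = "iksim_invalid_input")
  }
  structure(list(kon = kon, koff = koff, concentration_M = concentration_M,
                 competent = competent, bound_config = bound_config),
            class = "iks_binding_spec")
}

#' Dissociation constant of a binding spec
#' @param spec An [binding_spec()] object.
#' @return `koff / kon` in mol/L (NA if `kon == 0`).
#' @export
binding_kd <- function(spec) {
  stopifnot(inherits(spec, "iks_binding_spec"))
  if (spec$kon > 0) spec$koff / spec$kon else NA_real_
}

#' Expand a scheme with an explicit drug-bound copy
#'
#' Builds a 2N-state scheme: the original (unbound) states plus a bound
#' copy (labels suffixed `".b"`) carrying the bound drug configuration.
#' Binding edges run at `kon * C` from each binding-competent unbound
#' state to its bound twin and at `koff` back; no other cross-copy
#' transitions exist.  With `concentration_M = 0` the bound copy is
#' dynamically unreachable from an unbound start and the scheme reproduces
#' the unbound dynamics exactly.
#'
#' @param scheme An `iks_scheme`.
#' @param spec An [binding_spec()].
#' @return A 2N-state `iks_scheme`.
#' @export
augment_with_binding <- function(scheme, spec) {
  stopifnot(inherits(scheme, "iks_scheme"), inherits(spec, "iks_binding_spec"))
  missing_states <- setdiff(spec$competent, scheme$states$state)
  if (length(missing_states)) {
    abort(paste0("Binding-competent state(s) not in scheme: ",
                 paste(missing_states, collapse = ", ")),
          class = "iksim_config_error")
  }
  if (!length(spec$competent) && spec$concentration_M > 0) {
    abort("Empty binding-competent set with positive ligand concentration.",
          class = "iksim_config_error")
  }
  bound_suffix <- ".b"
  bound_states <- scheme$states
  bound_states$state <- paste0(bound_states$state, bound_suffix)

  bound_tr <- apply_drug_config(scheme, spec$bound_config)$transitions
  bound_tr$label <- paste0(bound_tr$label, bound_suffix)
  bound_tr$from <- paste0(bound_tr$from, bound_suffix)
  bound_tr$to <- paste0(bound_tr$to, bound_suffix)

  bind_tr <- tibble::tibble(
    label = c(paste0("on.", spec$competent), paste0("off.", spec$competent)),
    from = c(spec$competent, paste0(spec$competent, bound_suffix)),
    to = c(paste0(spec$competent, bound_suffix), spec$competent),
    amplitude = c(rep(spec$kon * spec$concentration_M, length(spec$competent)),
                  rep(spec$koff, length(spec$competent))),
    charge = 0)

  gating_scheme(
    states = dplyr::bind_rows(scheme$states, bound_states),
    transitions = dplyr::bind_rows(scheme$transitions, bound_tr, bind_tr),
    constants = scheme$constants,
    name = paste0(scheme$name, "+binding"))
}
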