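#include <Rcpp.h>
using namespace Rcpp;

// choice coding throughout: 1 = left touch, 0 = right touch.
// hidden-state coding (0-based here, 1-based in R): 0 = explore,
// 1 = exploit-left, 2 = exploit-right.

static inline double emit_prob(double emit_left, int choice) {
  return choice == 1 ? emit_left : 1.0 - emit_left;
}

// Negative log-likelihood of a choice/reward sequence under the RLCK agent.
// par = (alpha, beta, bias, kappa); the choice-kernel learning rate is tied
// to alpha so the model keeps exactly four free parameters.
// [[Rcpp::export]]
double rlck_nll_cpp(NumericVector par, IntegerVector choice,
                    IntegerVector reward) {
  const double alpha = par[0], beta = par[1], bias = par[2], kappa = par[3];
  double qL = 0.5, qR = 0.5, cL = 0.0, cR = 0.0;
  double nll = 0.0;
  const int n = choice.size();
  for (int t = 0; t < n; ++t) {
    const double z = beta * (qL - qR) + bias + kappa * (cL - cR);
    const double pL = 1.0 / (1.0 + std::exp(-z));
    double p = (choice[t] == 1) ? pL : 1.0 - pL;
    if (p < 1e-300) p = 1e-300;
    nll -= std::log(p);
    const double r = static_cast<double>(reward[t]);
    if (choice[t] == 1) {
      qL += alpha * (r - qL);
      cL += alpha * (1.0 - cL);
      cR += alpha * (0.0 - cR);
    } else {
      qR += alpha * (r - qR);
      cR += alpha * (1.0 - cR);
      cL += alpha * (0.0 - cL);
    }
  }
  return nll;
}

// Scaled forward recursion; returns the log marginal likelihood or -Inf for
// a sequence impossible under the (structurally zeroed) parameters.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix trans, NumericVector emit_left,
                       NumericVector init, IntegerVector choice) {
  const int T = choice.size();
  double a[3], an[3];
  double ll = 0.0;
  double c = 0.0;
  for (int j = 0; j < 3; ++j) {
    a[j] = init[j] * emit_prob(emit_left[j], choice[0]);
    c += a[j];
  }
  if (c <= 0.0) return R_NegInf;
  ll += std::log(c);
  for (int j = 0; j < 3; ++j) a[j] /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) s += a[i] * trans(i, j);
      an[j] = s * emit_prob(emit_left[j], choice[t]);
      c += an[j];
    }
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c);
    for (int j = 0; j < 3; ++j) a[j] = an[j] / c;
  }
  return ll;
}

// Forward-backward E-step for one sequence: per-trial posteriors gamma,
// summed transition posteriors xi, and the log-likelihood.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix trans, NumericVector emit_left,
                   NumericVector init, IntegerVector choice) {
  const int T = choice.size();
  NumericMatrix alpha(T, 3), beta(T, 3), gamma(T, 3), xi(3, 3);
  NumericVector cs(T);
  double ll = 0.0;

  double c = 0.0;
  for (int j = 0; j < 3; ++j) {
    alpha(0, j) = init[j] * emit_prob(emit_left[j], choice[0]);
    c += alpha(0, j);
  }
  if (c <= 0.0) stop("sequence has zero probability under the parameters");
  cs[0] = c;
  ll += std::log(c);
  for (int j = 0; j < 3; ++j) alpha(0, j) /= c;

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int i = 0; i < 3; ++i) s += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = s * emit_prob(emit_left[j], choice[t]);
      c += alpha(t, j);
    }
    if (c <= 0.0) stop("sequence has zero probability under the parameters");
    cs[t] = c;
    ll += std::log(c);
    for (int j = 0; j < 3; ++j) alpha(t, j) /= c;
  }

  for (int j = 0; j < 3; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j)
        s += trans(i, j) * emit_prob(emit_left[j], choice[t + 1]) *
             beta(t + 1, j);
      beta(t, i) = s / cs[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int j = 0; j < 3; ++j) {
      gamma(t, j) = alpha(t, j) * beta(t, j);
      g += gamma(t, j);
    }
    for (int j = 0; j < 3; ++j) gamma(t, j) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) {
        xi(i, j) += alpha(t, i) * trans(i, j) *
                    emit_prob(emit_left[j], choice[t + 1]) *
                    beta(t + 1, j) / cs[t + 1];
      }
    }
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi path in log space; ties resolve to the lowest state index so
// decoding is deterministic.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix trans, NumericVector emit_left,
                              NumericVector init, IntegerVector choice) {
  const int T = choice.size();
  NumericMatrix delta(T, 3);
  IntegerMatrix psi(T, 3);
  auto lg = [](double x) { return x > 0.0 ? std::log(x) : R_NegInf; };

  for (int j = 0; j < 3; ++j)
    delta(0, j) = lg(init[j]) + lg(emit_prob(emit_left[j], choice[0]));
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 3; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < 3; ++i) {
        const double v = delta(t - 1, i) + lg(trans(i, j));
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + lg(emit_prob(emit_left[j], choice[t]));
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int j = 0; j < 3; ++j)
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
  return path;
}

static inline double step_bound(double p, double p_min, double p_max,
                                bool reflect) {
  if (reflect) {
    if (p < p_min) p = 2.0 * p_min - p;
    if (p > p_max) p = 2.0 * p_max - p;
  }
  if (p < p_min) p = p_min;
  if (p > p_max) p = p_max;
  return p;
}

// One bandit session: drifting two-arm probability walk, latent
// explore/exploit chain, choices (exploit states emit their side, explore
// draws from the RLCK policy or uniformly), Bernoulli rewards, and RLCK
// value updates after every trial. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export]]
List simulate_session_cpp(int n_trials, double p_left0, double p_right0,
                          double step_prob, double step_size, double p_min,
                          double p_max, bool reflect, NumericMatrix trans,
                          NumericVector init, double explore_emit_left,
                          NumericVector agent, bool policy_rlck) {
  NumericVector p_left(n_trials), p_right(n_trials);
  IntegerVector state(n_trials), choice(n_trials), reward(n_trials);
  const double alpha = agent[0], beta = agent[1], bias = agent[2],
               kappa = agent[3];
  double qL = 0.5, qR = 0.5, cL = 0.0, cR = 0.0;
  double pl = p_left0, pr = p_right0;
  int s_prev = 0;

  for (int t = 0; t < n_trials; ++t) {
    p_left[t] = pl;
    p_right[t] = pr;

    // latent state
    double u = unif_rand();
    int s = 2;
    if (t == 0) {
      double acc = 0.0;
      for (int j = 0; j < 3; ++j) {
        acc += init[j];
        if (u <= acc) { s = j; break; }
      }
    } else {
      double acc = 0.0;
      for (int j = 0; j < 3; ++j) {
        acc += trans(s_prev, j);
        if (u <= acc) { s = j; break; }
      }
    }
    state[t] = s + 1;
    s_prev = s;

    // choice
    int ch;
    if (s == 1) {
      ch = 1;
    } else if (s == 2) {
      ch = 0;
    } else {
      double pL;
      if (policy_rlck) {
        const double z = beta * (qL - qR) + bias + kappa * (cL - cR);
        pL = 1.0 / (1.0 + std::exp(-z));
      } else {
        pL = explore_emit_left;
      }
      ch = (unif_rand() < pL) ? 1 : 0;
    }
    choice[t] = ch;

    // reward from the walk
    const double pr_t = (ch == 1) ? pl : pr;
    const int r = (unif_rand() < pr_t) ? 1 : 0;
    reward[t] = r;

    // agent update
    if (ch == 1) {
      qL += alpha * (r - qL);
      cL += alpha * (1.0 - cL);
      cR += alpha * (0.0 - cR);
    } else {
      qR += alpha * (r - qR);
      cR += alpha * (1.0 - cR);
      cL += alpha * (0.0 - cL);
    }

    // walk update for the next trial (left arm first, then right)
    if (t + 1 < n_trials) {
      if (unif_rand() < step_prob) {
        const double dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
        pl = step_bound(pl + dir * step_size, p_min, p_max, reflect);
      }
      if (unif_rand() < step_prob) {
        const double dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
        pr = step_bound(pr + dir * step_size, p_min, p_max, reflect);
      }
    }
  }

  return List::create(_["p_left"] = p_left, _["p_right"] = p_right,
                      _["state"] = state, _["choice"] = choice,
                      _["reward"] = reward);
}
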