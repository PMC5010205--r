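#include <Rcpp.h>
using namespace Rcpp;

// Per-trial simulation kernel shared by all model variants.
//
// RNG contract (must match the pure-R reference engine draw for draw):
//   1. one unif_rand() to select the action by inverse CDF on the softmax
//      probabilities (drawn even when there is a single action);
//   2. one norm_rand() for a Gaussian reward, or one unif_rand() mapped
//      through the outcome inverse CDF for a discrete reward.
// Prediction errors use the PRE-update weights / state value; the critic
// is updated after the actor, also from the pre-update V.
//
// model: 0 = AU / generalized AU (actor-based delta, decay beta, cross
//        term epsilon, clamped at 0)
//        1 = ACU (critic-based delta, decay = alpha, cross term epsilon)
//        2 = OpAL (critic-based delta scaled by the weight itself)

// [[Rcpp::export]]
List cpp_simulate(int model, List dists, NumericVector G0, NumericVector N0,
                  double V0, double alpha, double beta, double epsilon,
                  double a, double b, int n_trials, bool keep_log) {
  const int K = G0.size();
  std::vector<int> type(K);
  std::vector<double> mu(K), sigma(K);
  std::vector<std::vector<double>> out(K), cum(K);
  for (int k = 0; k < K; ++k) {
    List d = dists[k];
    std::string ty = as<std::string>(d["type"]);
    if (ty == "gaussian") {
      type[k] = 0;
      mu[k] = as<double>(d["mu"]);
      sigma[k] = as<double>(d["sigma"]);
    } else {
      type[k] = 1;
      NumericVector o = d["outcomes"], p = d["probs"];
      double c = 0.0;
      for (int j = 0; j < o.size(); ++j) {
        out[k].push_back(o[j]);
        c += p[j];
        cum[k].push_back(c);
      }
    }
  }

  NumericVector G = clone(G0), N = clone(N0);
  double V = V0;
  const bool has_critic = (model == 1 || model == 2);

  NumericMatrix Glog, Nlog;
  NumericVector Vlog, rlog;
  IntegerVector alog;
  if (keep_log) {
    Glog = NumericMatrix(n_trials, K);
    Nlog = NumericMatrix(n_trials, K);
    Vlog = NumericVector(n_trials);
    rlog = NumericVector(n_trials);
    alog = IntegerVector(n_trials);
  }

  std::vector<double> P(K);
  for (int t = 0; t < n_trials; ++t) {
    // softmax with max-shift (shift-invariant, guards overflow)
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      P[k] = a * G[k] - b * N[k];
      if (P[k] > m) m = P[k];
    }
    double Z = 0.0;
    for (int k = 0; k < K; ++k) {
      P[k] = std::exp(P[k] - m);
      Z += P[k];
    }
    for (int k = 0; k < K; ++k) P[k] /= Z;
    // bitwise identical to the R reference: u <= cumsum(P)
    double u = unif_rand(), c = 0.0;
    int i = K - 1;
    for (int k = 0; k < K; ++k) {
      c += P[k];
      if (u <= c) { i = k; break; }
    }

    // reward draw
    double r;
    if (type[i] == 0) {
      r = mu[i] + sigma[i] * norm_rand();
    } else {
      double ur = unif_rand();
      size_t j = 0, J = cum[i].size();
      while (j + 1 < J && ur > cum[i][j]) ++j;
      r = out[i][j];
    }

    // actor update from pre-update weights / value
    double delta = has_critic ? (r - V) : (r - (G[i] - N[i]));
    if (model == 2) {
      G[i] = std::max(G[i] * (1.0 + alpha * delta), 0.0);
      N[i] = std::max(N[i] * (1.0 - alpha * delta), 0.0);
    } else {
      double dec = (model == 1) ? alpha : beta;
      double pos = std::max(delta, 0.0), neg = std::max(-delta, 0.0);
      double g2 = G[i] + alpha * (pos - epsilon * neg) - dec * G[i];
      double n2 = N[i] + alpha * (neg - epsilon * pos) - dec * N[i];
      G[i] = std::max(g2, 0.0);
      N[i] = std::max(n2, 0.0);
    }
    if (has_critic) V += alpha * (r - V);

    if (keep_log) {
      for (int k = 0; k < K; ++k) {
        Glog(t, k) = G[k];
        Nlog(t, k) = N[k];
      }
      Vlog[t] = V;
      rlog[t] = r;
      alog[t] = i + 1;
    }
  }

  List res = List::create(
    _["G_final"] = G, _["N_final"] = N, _["V_final"] = V);
  if (keep_log) {
    res["G"] = Glog;
    res["N"] = Nlog;
    res["V"] = Vlog;
    res["reward"] = rlog;
    res["action"] = alog;
  }
  return res;
}

// Fraction of risky (action 2) choices of the AU learner on the
// safe-versus-risky lever task, learning and choosing concurrently.
// Tight kernel for the sum-of-squared-errors objective of the fitting
// procedure, where it is evaluated hundreds of times per simplex run.
// Same RNG contract as cpp_simulate.

// [[Rcpp::export]]
double cpp_au_risky_fraction(double p_large, double alpha, double beta,
                             double epsilon, double a, double b,
                             int n_trials) {
  double G1 = 0, N1 = 0, G2 = 0, N2 = 0;
  int n_risky = 0;
  for (int t = 0; t < n_trials; ++t) {
    double x1 = a * G1 - b * N1, x2 = a * G2 - b * N2;
    double m = std::max(x1, x2);
    double e1 = std::exp(x1 - m), e2 = std::exp(x2 - m);
    double p1 = e1 / (e1 + e2);
    double u = unif_rand();
    bool risky = (u > p1);
    double r;
    if (risky) {
      ++n_risky;
      double ur = unif_rand();
      r = (ur <= p_large) ? 4.0 : 0.0;
    } else {
      (void)unif_rand();  // keep the stream aligned with cpp_simulate
      r = 1.0;
    }
    double &G = risky ? G2 : G1, &Nw = risky ? N2 : N1;
    double delta = r - (G - Nw);
    double pos = std::max(delta, 0.0), neg = std::max(-delta, 0.0);
    double g2 = G + alpha * (pos - epsilon * neg) - beta * G;
    double n2 = Nw + alpha * (neg - epsilon * pos) - beta * Nw;
    G = std::max(g2, 0.0);
    Nw = std::max(n2, 0.0);
  }
  return (double)n_risky / (double)n_trials;
}
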