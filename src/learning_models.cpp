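#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trial-level engine for the five trait-utility learning models.
//
// Conventions (shared with the R wrappers):
//  * `par` holds natural-space parameters in the canonical order
//    documented in model_spec():
//      model 1: beta0, beta1, sigma
//      model 2: alpha, sigma
//      model 3: alpha_plus, alpha_minus, sigma
//      model 4: alpha, gamma, sigma
//      model 5: alpha_plus, alpha_minus, gamma, sigma
//  * `sim` is the T x T similarity matrix already re-ordered to the
//    session's trial order, so sim(i, t) is the similarity between the
//    traits shown on trials i+1 and t+1.
//  * Prediction error on trial i is PE(i) = F(i) - U(i), the feedback
//    minus the stated (or simulated) utility response; missed trials
//    contribute no update.
//  * Asymmetric-rate models pick alpha_plus when the feedback lies
//    closer to the self-rating than the trial's prediction does
//    (|F - S| < |P - S|); ties and the opposite case use alpha_minus.
//    `compare_learning` switches the comparison point from the emitted
//    prediction P to the learning component Pm (models 4-5 only).

struct ModelPars {
  double alpha_p, alpha_m, gamma, sigma, beta0, beta1;
  bool dual_rate, mixed;
};

static ModelPars unpack(int model_id, const NumericVector& par) {
  ModelPars p;
  p.alpha_p = p.alpha_m = p.gamma = 0.0;
  p.beta0 = p.beta1 = 0.0;
  p.dual_rate = (model_id == 3 || model_id == 5);
  p.mixed = (model_id == 4 || model_id == 5);
  switch (model_id) {
  case 1:
    p.beta0 = par[0]; p.beta1 = par[1]; p.sigma = par[2];
    break;
  case 2:
    p.alpha_p = p.alpha_m = par[0]; p.sigma = par[1];
    break;
  case 3:
    p.alpha_p = par[0]; p.alpha_m = par[1]; p.sigma = par[2];
    break;
  case 4:
    p.alpha_p = p.alpha_m = par[0]; p.gamma = par[1]; p.sigma = par[2];
    break;
  case 5:
    p.alpha_p = par[0]; p.alpha_m = par[1]; p.gamma = par[2];
    p.sigma = par[3];
    break;
  default:
    stop("unknown model_id");
  }
  return p;
}

// Core forward pass. When `simulate` is true, responses are generated
// closed-loop as U(t) = clip(round(P(t) + sigma * eps(t)), 1, 100).
static void forward(int model_id, const ModelPars& p,
                    const NumericVector& S, const NumericVector& F,
                    NumericVector& U, const NumericMatrix& sim,
                    const NumericVector& p_init, bool compare_learning,
                    bool simulate, const NumericVector& eps,
                    NumericVector& P, NumericVector& Pm,
                    NumericVector& PE) {
  int T = S.size();
  std::vector<double> acc(T, 0.0);
  for (int t = 0; t < T; ++t) {
    if (model_id == 1) {
      Pm[t] = P[t] = p.beta0 + p.beta1 * S[t];
    } else {
      Pm[t] = p_init[t] + acc[t];
      P[t] = p.mixed ? p.gamma * S[t] + (1.0 - p.gamma) * Pm[t] : Pm[t];
    }
    if (simulate) {
      double u = std::round(P[t] + p.sigma * eps[t]);
      if (u < 1.0) u = 1.0;
      if (u > 100.0) u = 100.0;
      U[t] = u;
    }
    if (NumericVector::is_na(U[t])) continue;
    PE[t] = F[t] - U[t];
    if (model_id == 1) continue;
    double a = p.alpha_p;
    if (p.dual_rate) {
      double ref = compare_learning ? Pm[t] : P[t];
      a = (std::fabs(F[t] - S[t]) < std::fabs(ref - S[t])) ? p.alpha_p
                                                           : p.alpha_m;
    }
    double w = a * PE[t];
    for (int k = t + 1; k < T; ++k) acc[k] += w * sim(t, k);
  }
}

// [[Rcpp::export(name = ".traj_cpp")]]
List traj_cpp(int model_id, NumericVector par, NumericVector S,
              NumericVector F, NumericVector U, NumericMatrix sim,
              NumericVector p_init, bool compare_learning) {
  int T = S.size();
  ModelPars p = unpack(model_id, par);
  NumericVector P(T), Pm(T), PE(T, NA_REAL), Uc = clone(U);
  NumericVector eps(0);
  forward(model_id, p, S, F, Uc, sim, p_init, compare_learning, false,
          eps, P, Pm, PE);
  return List::create(_["P"] = P, _["Pm"] = Pm, _["PE"] = PE);
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(int model_id, NumericVector par, NumericVector S,
                  NumericVector F, NumericMatrix sim,
                  NumericVector p_init, NumericVector eps,
                  bool compare_learning) {
  int T = S.size();
  ModelPars p = unpack(model_id, par);
  NumericVector P(T), Pm(T), PE(T, NA_REAL), U(T, NA_REAL);
  forward(model_id, p, S, F, U, sim, p_init, compare_learning, true,
          eps, P, Pm, PE);
  return List::create(_["U"] = U, _["P"] = P, _["Pm"] = Pm,
                      _["PE"] = PE);
}

static double loglik_nat(int model_id, const NumericVector& par,
                         const NumericVector& S, const NumericVector& F,
                         const NumericVector& U, const NumericMatrix& sim,
                         const NumericVector& p_init,
                         bool compare_learning) {
  int T = S.size();
  ModelPars p = unpack(model_id, par);
  NumericVector P(T), Pm(T), PE(T, NA_REAL), Uc = clone(const_cast<NumericVector&>(U));
  NumericVector eps(0);
  forward(model_id, p, S, F, Uc, sim, p_init, compare_learning, false,
          eps, P, Pm, PE);
  double ll = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (int t = 0; t < T; ++t) {
    if (NumericVector::is_na(U[t])) continue;
    double r = (U[t] - P[t]) / p.sigma;
    ll += -0.5 * (l2pi + r * r) - std::log(p.sigma);
  }
  return ll;
}

// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(int model_id, NumericVector par, NumericVector S,
                  NumericVector F, NumericVector U, NumericMatrix sim,
                  NumericVector p_init, bool compare_learning) {
  return loglik_nat(model_id, par, S, F, U, sim, p_init, compare_learning);
}

// Transform codes per parameter: 0 identity, 1 logistic (unit
// interval), 2 exponential (positive).
static NumericVector z_to_nat(const NumericVector& z,
                              const IntegerVector& codes,
                              double sigma_fixed) {
  int d = z.size();
  bool fix = !NumericVector::is_na(sigma_fixed);
  NumericVector par(codes.size());
  for (int j = 0; j < d; ++j) {
    switch (codes[j]) {
    case 1: par[j] = 1.0 / (1.0 + std::exp(-z[j])); break;
    case 2: par[j] = std::exp(z[j]); break;
    default: par[j] = z[j];
    }
  }
  if (fix) par[codes.size() - 1] = sigma_fixed;
  return par;
}

// Negative log posterior in transformed space (independent Gaussian
// prior on each transformed coordinate).
static double nlp_val(int model_id, const NumericVector& z,
                      const IntegerVector& codes, double sigma_fixed,
                      const NumericVector& prior_mean,
                      const NumericVector& prior_sd,
                      const NumericVector& S, const NumericVector& F,
                      const NumericVector& U, const NumericMatrix& sim,
                      const NumericVector& p_init, bool compare_learning) {
  NumericVector par = z_to_nat(z, codes, sigma_fixed);
  double ll = loglik_nat(model_id, par, S, F, U, sim, p_init,
                         compare_learning);
  double lp = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (int j = 0; j < z.size(); ++j) {
    double r = (z[j] - prior_mean[j]) / prior_sd[j];
    lp += -0.5 * (l2pi + r * r) - std::log(prior_sd[j]);
  }
  return -(ll + lp);
}

// [[Rcpp::export(name = ".nlp_cpp")]]
double nlp_cpp(int model_id, NumericVector z, IntegerVector codes,
               double sigma_fixed, NumericVector prior_mean,
               NumericVector prior_sd, NumericVector S, NumericVector F,
               NumericVector U, NumericMatrix sim, NumericVector p_init,
               bool compare_learning) {
  return nlp_val(model_id, z, codes, sigma_fixed, prior_mean, prior_sd,
                 S, F, U, sim, p_init, compare_learning);
}

// Central-difference gradient of the negative log posterior.
// [[Rcpp::export(name = ".nlp_grad_cpp")]]
NumericVector nlp_grad_cpp(int model_id, NumericVector z,
                           IntegerVector codes, double sigma_fixed,
                           NumericVector prior_mean,
                           NumericVector prior_sd, NumericVector S,
                           NumericVector F, NumericVector U,
                           NumericMatrix sim, NumericVector p_init,
                           bool compare_learning) {
  int d = z.size();
  NumericVector g(d), zz = clone(z);
  for (int j = 0; j < d; ++j) {
    double h = 1e-5 * (1.0 + std::fabs(z[j]));
    double z0 = zz[j];
    zz[j] = z0 + h;
    double fp = nlp_val(model_id, zz, codes, sigma_fixed, prior_mean,
                        prior_sd, S, F, U, sim, p_init, compare_learning);
    zz[j] = z0 - h;
    double fm = nlp_val(model_id, zz, codes, sigma_fixed, prior_mean,
                        prior_sd, S, F, U, sim, p_init, compare_learning);
    zz[j] = z0;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}
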