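#include <Rcpp.h>
using namespace Rcpp;

// Observation-level log-likelihood of one cell.  Censored cells contribute
// log sum_{y=1}^{5} Poisson(y; mu); the partial sum is evaluated with a
// nested product, exact in double precision for any positive mu.
static inline double cell_loglik(double y, int cens, double E, double loglam) {
  double mu = E * std::exp(loglam);
  if (cens) {
    double s = mu * (1.0 + (mu / 2.0) * (1.0 + (mu / 3.0) *
               (1.0 + (mu / 4.0) * (1.0 + mu / 5.0))));
    return -mu + std::log(s);
  }
  return R::dpois(y, mu, 1);
}

// index helpers: arrays are stored in R's column-major layout
// y/cens/E/eps: (I x J x K), f: (I x J x m)
static inline int idx3(int i, int j, int k, int I, int J) {
  return i + I * (j + J * k);
}

// [[Rcpp::export]]
double cpp_full_loglik(NumericVector y, IntegerVector cens, NumericVector E,
                       NumericMatrix M, NumericVector f, NumericVector eps,
                       int I, int J, int K, int m) {
  double ll = 0.0;
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        double lp = eps[idx3(i, j, k, I, J)];
        for (int mm = 0; mm < m; ++mm)
          lp += M(k, mm) * f[idx3(i, j, mm, I, J)];
        int c = idx3(i, j, k, I, J);
        ll += cell_loglik(y[c], cens[c], E[c], lp);
      }
  return ll;
}

// One full systematic sweep of single-site random-walk MH updates of the
// latent factor field.  The prior is the pairwise-difference ICAR density of
// the AR(1) innovations plus a proper statewide-mean completion with
// precision `level_prec` on the mean innovation of each year.  The
// likelihood is evaluated through the identified product M = L Q.
// `f` is modified in place (callers pass a copy).  Returns accept count.
// [[Rcpp::export]]
int cpp_factor_sweep(NumericVector y, IntegerVector cens, NumericVector E,
                     NumericMatrix M, NumericVector f, NumericVector eps,
                     NumericMatrix mu, NumericVector eta,
                     IntegerVector nbr, IntegerVector ptr,
                     double sd, int I, int J, int K, int m,
                     int prior_only, double level_prec) {
  int acc = 0;
  std::vector<double> ebar(J);
  for (int mm = 0; mm < m; ++mm) {
    double et = eta[mm];
    // innovation e(i,j) for factor mm
    auto innov = [&](int i, int j) {
      double e = f[idx3(i, j, mm, I, J)] - mu(j, mm);
      if (j > 0) e -= et * (f[idx3(i, j - 1, mm, I, J)] - mu(j - 1, mm));
      return e;
    };
    for (int j = 0; j < J; ++j) {
      double s = 0.0;
      for (int i = 0; i < I; ++i) s += innov(i, j);
      ebar[j] = s / I;
    }
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < I; ++i) {
        double x = f[idx3(i, j, mm, I, J)];
        double xp = x + sd * norm_rand();
        double dx = xp - x;
        double d = 0.0;
        if (!prior_only) {
          for (int k = 0; k < K; ++k) {
            double lp = eps[idx3(i, j, k, I, J)];
            for (int m2 = 0; m2 < m; ++m2)
              lp += M(k, m2) * f[idx3(i, j, m2, I, J)];
            int c = idx3(i, j, k, I, J);
            d += cell_loglik(y[c], cens[c], E[c], lp + M(k, mm) * dx) -
                 cell_loglik(y[c], cens[c], E[c], lp);
          }
        }
        // prior, year j pairwise terms
        double ec = innov(i, j), ep = ec + dx;
        for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
          double el = innov(nbr[p], j);
          d -= 0.5 * ((ep - el) * (ep - el) - (ec - el) * (ec - el));
        }
        // prior, year j+1 pairwise terms (x enters through -eta * x)
        if (j + 1 < J) {
          double ec2 = innov(i, j + 1), ep2 = ec2 - et * dx;
          for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
            double el = innov(nbr[p], j + 1);
            d -= 0.5 * ((ep2 - el) * (ep2 - el) - (ec2 - el) * (ec2 - el));
          }
        }
        // statewide-mean completion
        double ebn = ebar[j] + dx / I;
        d -= 0.5 * level_prec * (ebn * ebn - ebar[j] * ebar[j]);
        double eb2n = 0.0;
        if (j + 1 < J) {
          eb2n = ebar[j + 1] - et * dx / I;
          d -= 0.5 * level_prec * (eb2n * eb2n - ebar[j + 1] * ebar[j + 1]);
        }
        if (std::log(unif_rand()) < d) {
          f[idx3(i, j, mm, I, J)] = xp;
          ebar[j] = ebn;
          if (j + 1 < J) ebar[j + 1] = eb2n;
          ++acc;
        }
      }
    }
  }
  return acc;
}

// One sweep of single-site random-walk MH updates of the uncorrelated
// heterogeneity terms epsilon_ijk against Poisson/interval likelihood times
// N(0, sigma2_k).  `eps` modified in place (callers pass a copy).
// [[Rcpp::export]]
int cpp_eps_sweep(NumericVector y, IntegerVector cens, NumericVector E,
                  NumericMatrix M, NumericVector f, NumericVector eps,
                  NumericVector sigma2, double sd,
                  int I, int J, int K, int m) {
  int acc = 0;
  for (int k = 0; k < K; ++k) {
    double sdk = std::sqrt(sigma2[k]);
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        double base = 0.0;
        for (int mm = 0; mm < m; ++mm)
          base += M(k, mm) * f[idx3(i, j, mm, I, J)];
        int c = idx3(i, j, k, I, J);
        double e0 = eps[c];
        double e1 = e0 + sd * norm_rand();
        double d = cell_loglik(y[c], cens[c], E[c], base + e1) -
                   cell_loglik(y[c], cens[c], E[c], base + e0) +
                   R::dnorm(e1, 0.0, sdk, 1) - R::dnorm(e0, 0.0, sdk, 1);
        if (std::log(unif_rand()) < d) {
          eps[c] = e1;
          ++acc;
        }
      }
  }
  return acc;
}
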