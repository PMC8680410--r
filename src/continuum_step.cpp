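#include <Rcpp.h>
using namespace Rcpp;

// Five-point Laplacian with reflecting (zero-flux) boundaries via ghost
// mirroring: an out-of-range neighbour is replaced by the centre value,
// i.e. contributes zero flux. Dirichlet conditions are imposed outside
// the stepper by overwriting boundary rings.
static inline double lap(const NumericMatrix& x, int i, int j,
                         int nr, int nc) {
  const double c = x(i, j);
  const double up    = (i > 0)      ? x(i - 1, j) : c;
  const double down  = (i < nr - 1) ? x(i + 1, j) : c;
  const double left  = (j > 0)      ? x(i, j - 1) : c;
  const double right = (j < nc - 1) ? x(i, j + 1) : c;
  return up + down + left + right - 4.0 * c;
}

// One explicit Euler step of the five tissue fields. Matrices are the
// current state; bead sites are 1-based (row, col); ec/perf masks mark
// endothelial-agent and perfused-vessel sites. Returns the updated
// fields (inputs untouched) plus a finiteness flag.
// [[Rcpp::export(name = ".step_fields_cpp")]]
List step_fields_cpp(NumericMatrix c, NumericMatrix g, NumericMatrix m,
                     NumericMatrix f, NumericMatrix mf,
                     IntegerVector bead_row, IntegerVector bead_col,
                     double bead_G, double bead_H, double bead_h,
                     double bead_tau, double t_now,
                     LogicalMatrix ec_mask, LogicalMatrix perf_mask,
                     List par) {
  const int nr = c.nrow(), nc = c.ncol();
  const double dt        = par["dt"];
  const double inv_dx2   = par["inv_dx2"];
  const double D_c       = par["D_oxygen"];
  const double D_g       = par["D_vegf"];
  const double D_m       = par["D_cell"];
  const double k_cons    = par["k_consume"];
  const double K_cons    = par["K_consume"];
  const double p_vegf    = par["p_vegf_progenitor"];
  const double fib_mult  = par["fibroblast_vegf_multiplier"];
  const double phi_max   = par["phi_max"];
  const double K_phi     = par["K_phi"];
  const double q_phi     = par["q_phi"];
  const double lambda_g  = par["lambda_vegf"];
  const double u_ec      = par["u_ec"];
  const double r_prolif  = par["r_prolif"];
  const double d_anoxic  = par["d_anoxic"];
  const double cap       = par["carrying_capacity"];
  const double r_matrix  = par["r_matrix"];
  const double c_anoxia  = par["c_anoxia"];
  const double c_vessel  = par["c_vessel"];
  const double v_rate    = par["vessel_relax_rate"];

  NumericMatrix cn(nr, nc), gn(nr, nc), mn(nr, nc), fn(nr, nc), mfn(nr, nc);
  const double Kq = std::pow(K_phi, q_phi);
  bool finite = true;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double ci = c(i, j), gi = g(i, j), mi = m(i, j),
                   fi = f(i, j), mfi = mf(i, j);
      const double cells = mi + fi;
      const double mich = ci / (ci + K_cons);

      double dc = D_c * inv_dx2 * lap(c, i, j, nr, nc)
                - k_cons * cells * mich;
      if (perf_mask(i, j)) dc += v_rate * (c_vessel - ci);

      const double phi = 1.0 + (phi_max - 1.0) * Kq /
                         (std::pow(ci, q_phi) + Kq);
      double dg = D_g * inv_dx2 * lap(g, i, j, nr, nc)
                + (p_vegf * mi + fib_mult * p_vegf * fi) * phi
                - lambda_g * gi;
      if (ec_mask(i, j)) dg -= u_ec * gi;

      const double logistic = 1.0 - cells / cap;
      const double death = (ci < c_anoxia) ? d_anoxic : 0.0;
      const double dm = D_m * inv_dx2 * lap(m, i, j, nr, nc)
                      + r_prolif * mich * mi * logistic - death * mi;
      const double df = D_m * inv_dx2 * lap(f, i, j, nr, nc)
                      + r_prolif * mich * fi * logistic - death * fi;
      const double dmf = r_matrix * cells * (1.0 - mfi);

      cn(i, j)  = ci + dt * dc;
      gn(i, j)  = gi + dt * dg;
      mn(i, j)  = mi + dt * dm;
      fn(i, j)  = fi + dt * df;
      mfn(i, j) = mfi + dt * dmf;
    }
  }

  // Bead sources use the local (pre-step) oxygen through the Hill gate.
  const double Hh = std::pow(bead_H, bead_h);
  const double decay = std::exp(-bead_tau * t_now);
  const int nb = bead_row.size();
  for (int b = 0; b < nb; ++b) {
    const int i = bead_row[b] - 1, j = bead_col[b] - 1;
    const double ci = c(i, j);
    const double rate = bead_G * Hh / (std::pow(ci, bead_h) + Hh) * decay;
    cn(i, j) += dt * rate;
  }

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!R_finite(cn(i, j)) || !R_finite(gn(i, j)) ||
          !R_finite(mn(i, j)) || !R_finite(fn(i, j)) ||
          !R_finite(mfn(i, j))) { finite = false; }
      if (cn(i, j) < 0) cn(i, j) = 0;
      if (gn(i, j) < 0) gn(i, j) = 0;
      if (mn(i, j) < 0) mn(i, j) = 0;
      if (fn(i, j) < 0) fn(i, j) = 0;
      if (mfn(i, j) < 0) mfn(i, j) = 0;
    }
  }

  return List::create(_["oxygen"] = cn, _["vegf"] = gn,
                      _["progenitor"] = mn, _["fibroblast"] = fn,
                      _["fibrous"] = mfn, _["finite"] = finite);
}
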