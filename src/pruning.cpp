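#include <Rcpp.h>
using namespace Rcpp;

// Post-order evaluation of the MGPM log-likelihood.
//
// Each non-root node v owns the edge to its parent, with Gaussian transition
// x_v | x_pa ~ N(a*x_pa + b, V).  The partial likelihood of the subtree below
// a node, as a function of the *parent's* state x, is carried as a log-scale
// quadratic q(x) = 0.5*P*x^2 + M*x + C; sibling messages add coefficient-wise,
// and integrating an internal node's state against its own edge transition is
// a closed-form Gaussian integral.  Edges must arrive child-before-parent
// (ape "postorder").
//
// V == 0 on an internal edge composes exactly as a Dirac (affine pass-through);
// V == 0 on a terminal edge makes the data density degenerate -> -Inf.
// [[Rcpp::export]]
double C_pruning_loglik(IntegerVector pa, IntegerVector ch,
                        NumericVector a, NumericVector b, NumericVector V,
                        NumericVector tipval, LogicalVector is_tip,
                        int nnode, int root, double x0) {
  std::vector<double> P(nnode, 0.0), M(nnode, 0.0), C(nnode, 0.0);
  const double LOG2PI = 1.837877066409345483560659;
  const int ne = pa.size();
  for (int e = 0; e < ne; e++) {
    const int p = pa[e] - 1, c = ch[e] - 1;
    const double ae = a[e], be = b[e], Ve = V[e];
    double Pp, Mp, Cp;
    if (is_tip[c]) {
      if (Ve <= 0.0) return R_NegInf;
      const double r = tipval[c] - be;
      Pp = -ae * ae / Ve;
      Mp = ae * r / Ve;
      Cp = -r * r / (2.0 * Ve) - 0.5 * (LOG2PI + std::log(Ve));
    } else {
      const double Pc = P[c], Mc = M[c], Cc = C[c];
      if (Ve <= 0.0) {
        Pp = ae * ae * Pc;
        Mp = ae * (Pc * be + Mc);
        Cp = 0.5 * Pc * be * be + Mc * be + Cc;
      } else {
        // A = 1/V - P stays positive because P <= 0 on every message
        const double A = 1.0 / Ve - Pc;
        if (!(A > 0.0)) return R_NaN;
        const double Bc = Mc + be / Ve;
        Pp = -ae * ae / Ve + ae * ae / (Ve * Ve * A);
        Mp = -ae * be / Ve + ae * Bc / (Ve * A);
        Cp = Cc - 0.5 * std::log(Ve * A) - be * be / (2.0 * Ve) + Bc * Bc / (2.0 * A);
      }
    }
    if (ISNAN(Pp) || ISNAN(Mp) || ISNAN(Cp)) {
      // overflow in intermediate algebra (e.g. V = Inf): treat as impossible
      return R_NegInf;
    }
    P[p] += Pp; M[p] += Mp; C[p] += Cp;
  }
  const int r = root - 1;
  return 0.5 * P[r] * x0 * x0 + M[r] * x0 + C[r];
}
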