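#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Hot training loops. Semantics mirror the R-level single-step updates
// (backprop_update / quickprop_update); a test asserts the equivalence.
// All weight/memory matrices are modified in place, so the R caller
// passes private copies. The dense hidden-output layer goes through
// BLAS; the localist input layer touches only active columns.

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static const int INC1 = 1;
static const double ONE = 1.0, ZERO = 0.0;

struct ItemCodes {
  std::vector<const int*> ptr;
  std::vector<int> len;
  explicit ItemCodes(List x_idx) {
    const int n = x_idx.size();
    ptr.resize(n); len.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector v = x_idx[i];
      ptr[i] = INTEGER(v); len[i] = v.size();
    }
  }
};

// hidden activations for one item: h = sigmoid(b_h + sum of active cols)
static void hidden_forward(const double* Wih, const double* bh, int nh,
                           const int* idx, int nidx, double* h) {
  std::fill(h, h + nh, 0.0);
  for (int c = 0; c < nidx; ++c) {
    const double* col = Wih + (long)(idx[c] - 1) * nh;
    for (int j = 0; j < nh; ++j) h[j] += col[j];
  }
  for (int j = 0; j < nh; ++j) h[j] = sigmoid(bh[j] + h[j]);
}

// One forward/backward pass per presentation, online delta-rule updates
// with momentum. x_idx holds 1-based active input-unit indices per item;
// orders is presentations x epochs, 1-based item rows of targets.
// [[Rcpp::export(rng = false)]]
void bp_train_chunk(NumericMatrix W_ih, NumericVector b_h,
                    NumericMatrix W_ho, NumericVector b_o,
                    NumericMatrix D_Wih, NumericVector D_bh,
                    NumericMatrix D_Who, NumericVector D_bo,
                    List x_idx, NumericMatrix targets,
                    IntegerMatrix orders, double lr, double mom) {
  const int nh = W_ih.nrow(), ni = W_ih.ncol(), no = W_ho.nrow();
  const int npres = orders.nrow(), nep = orders.ncol();
  const int nitem = targets.nrow();
  const long nwih = (long)nh * ni, nwho = (long)no * nh;

  double* Wih = W_ih.begin(); double* bh = b_h.begin();
  double* Who = W_ho.begin(); double* bo = b_o.begin();
  double* DWih = D_Wih.begin(); double* Dbh = D_bh.begin();
  double* DWho = D_Who.begin(); double* Dbo = D_bo.begin();
  const double* tg = targets.begin();
  const int* ord = orders.begin();

  std::vector<double> h(nh), d_h(nh), o(no), d_o(no);
  ItemCodes codes(x_idx);
  const double neg_lr = -lr;
  const int niwih = (int)nwih, niwho = (int)nwho;

  for (long p = 0; p < (long)nep * npres; ++p) {
    const int item = ord[p] - 1;
    const int* idx = codes.ptr[item];
    const int nidx = codes.len[item];

    hidden_forward(Wih, bh, nh, idx, nidx, h.data());

    // o = sigmoid(b_o + W_ho h)
    F77_CALL(dgemv)("N", &no, &nh, &ONE, Who, &no, h.data(), &INC1,
                    &ZERO, o.data(), &INC1 FCONE);
    for (int k = 0; k < no; ++k) {
      const double ok = sigmoid(bo[k] + o[k]);
      o[k] = ok;
      d_o[k] = (ok - tg[item + (long)k * nitem]) * ok * (1.0 - ok);
    }
    // d_h = (W_ho^T d_o) * h (1 - h)
    F77_CALL(dgemv)("T", &no, &nh, &ONE, Who, &no, d_o.data(), &INC1,
                    &ZERO, d_h.data(), &INC1 FCONE);
    for (int j = 0; j < nh; ++j) d_h[j] *= h[j] * (1.0 - h[j]);

    // D_Who = mom D_Who - lr d_o h^T ;  W_ho += D_Who
    if (mom != 0.0)
      F77_CALL(dscal)(&niwho, &mom, DWho, &INC1);
    else
      std::fill(DWho, DWho + nwho, 0.0);
    F77_CALL(dger)(&no, &nh, &neg_lr, d_o.data(), &INC1, h.data(), &INC1,
                   DWho, &no);
    F77_CALL(daxpy)(&niwho, &ONE, DWho, &INC1, Who, &INC1);
    for (int k = 0; k < no; ++k) {
      const double upd = mom * Dbo[k] - lr * d_o[k];
      Dbo[k] = upd; bo[k] += upd;
    }

    // input layer: decay the whole memory, fresh gradient only on the
    // active columns (x is 0/1 localist; slot-major indices distinct)
    if (mom != 0.0)
      F77_CALL(dscal)(&niwih, &mom, DWih, &INC1);
    else
      std::fill(DWih, DWih + nwih, 0.0);
    for (int c = 0; c < nidx; ++c) {
      double* dcol = DWih + (long)(idx[c] - 1) * nh;
      for (int j = 0; j < nh; ++j) dcol[j] -= lr * d_h[j];
    }
    F77_CALL(daxpy)(&niwih, &ONE, DWih, &INC1, Wih, &INC1);
    for (int j = 0; j < nh; ++j) {
      const double upd = mom * Dbh[j] - lr * d_h[j];
      Dbh[j] = upd; bh[j] += upd;
    }
  }
}

// Fahlman's per-weight rule: quadratic (secant) step toward the
// parabola vertex, maximum-growth step mu*prev when the vertex lies
// beyond it, additive gradient term while the slope keeps its sign,
// plain gradient bootstrap without history.
static inline double qp_step(double g, double g_prev, double prev_step,
                             double lr, double mu) {
  if (prev_step == 0.0) return -lr * g;
  const bool same = g * g_prev > 0.0;
  double step;
  if (same && std::fabs(g) >= (mu / (1.0 + mu)) * std::fabs(g_prev))
    step = mu * prev_step;
  else if (g != 0.0)
    step = prev_step * g / (g_prev - g);
  else
    step = 0.0;
  if (same) step += -lr * g;
  return step;
}

// Batch Quickprop: one update per epoch from the gradient accumulated
// over the whole presentation list; sigmoid-prime offset 0.1 on the
// output derivative (flat-spot elimination), as in the standard
// published algorithm.
// [[Rcpp::export(rng = false)]]
void qp_train_chunk(NumericMatrix W_ih, NumericVector b_h,
                    NumericMatrix W_ho, NumericVector b_o,
                    NumericMatrix D_Wih, NumericVector D_bh,
                    NumericMatrix D_Who, NumericVector D_bo,
                    NumericMatrix G_Wih, NumericVector G_bh,
                    NumericMatrix G_Who, NumericVector G_bo,
                    List x_idx, NumericMatrix targets,
                    IntegerMatrix orders, double lr, double mu,
                    double decay) {
  const int nh = W_ih.nrow(), ni = W_ih.ncol(), no = W_ho.nrow();
  const int npres = orders.nrow(), nep = orders.ncol();
  const int nitem = targets.nrow();
  const long nwih = (long)nh * ni, nwho = (long)no * nh;

  double* Wih = W_ih.begin(); double* bh = b_h.begin();
  double* Who = W_ho.begin(); double* bo = b_o.begin();
  const double* tg = targets.begin();
  const int* ord = orders.begin();

  std::vector<double> h(nh), d_h(nh), o(no), d_o(no);
  std::vector<double> gWih(nwih), gWho(nwho), gbh(nh), gbo(no);
  ItemCodes codes(x_idx);

  for (int e = 0; e < nep; ++e) {
    std::fill(gWih.begin(), gWih.end(), 0.0);
    std::fill(gWho.begin(), gWho.end(), 0.0);
    std::fill(gbh.begin(), gbh.end(), 0.0);
    std::fill(gbo.begin(), gbo.end(), 0.0);

    for (int p = 0; p < npres; ++p) {
      const int item = ord[(long)e * npres + p] - 1;
      const int* idx = codes.ptr[item];
      const int nidx = codes.len[item];

      hidden_forward(Wih, bh, nh, idx, nidx, h.data());
      F77_CALL(dgemv)("N", &no, &nh, &ONE, Who, &no, h.data(), &INC1,
                      &ZERO, o.data(), &INC1 FCONE);
      for (int k = 0; k < no; ++k) {
        const double ok = sigmoid(bo[k] + o[k]);
        o[k] = ok;
        d_o[k] = (ok - tg[item + (long)k * nitem]) *
                 (ok * (1.0 - ok) + 0.1);
        gbo[k] += d_o[k];
      }
      F77_CALL(dgemv)("T", &no, &nh, &ONE, Who, &no, d_o.data(), &INC1,
                      &ZERO, d_h.data(), &INC1 FCONE);
      for (int j = 0; j < nh; ++j) {
        d_h[j] *= h[j] * (1.0 - h[j]);
        gbh[j] += d_h[j];
      }
      F77_CALL(dger)(&no, &nh, &ONE, d_o.data(), &INC1, h.data(), &INC1,
                     gWho.data(), &no);
      for (int c = 0; c < nidx; ++c) {
        double* gcol = gWih.data() + (long)(idx[c] - 1) * nh;
        for (int j = 0; j < nh; ++j) gcol[j] += d_h[j];
      }
    }

    // weight decay folded into the slope: the standard safeguard that
    // keeps maximum-growth steps from escalating weights without bound
    double* DWih = D_Wih.begin(); double* GWih = G_Wih.begin();
    for (long i = 0; i < nwih; ++i) {
      const double g = gWih[i] + decay * Wih[i];
      const double s = qp_step(g, GWih[i], DWih[i], lr, mu);
      Wih[i] += s; DWih[i] = s; GWih[i] = g;
    }
    double* DWho = D_Who.begin(); double* GWho = G_Who.begin();
    for (long i = 0; i < nwho; ++i) {
      const double g = gWho[i] + decay * Who[i];
      const double s = qp_step(g, GWho[i], DWho[i], lr, mu);
      Who[i] += s; DWho[i] = s; GWho[i] = g;
    }
    double* Dbh = D_bh.begin(); double* Gbh = G_bh.begin();
    for (int j = 0; j < nh; ++j) {
      const double g = gbh[j] + decay * bh[j];
      const double s = qp_step(g, Gbh[j], Dbh[j], lr, mu);
      bh[j] += s; Dbh[j] = s; Gbh[j] = g;
    }
    double* Dbo = D_bo.begin(); double* Gbo = G_bo.begin();
    for (int k = 0; k < no; ++k) {
      const double g = gbo[k] + decay * bo[k];
      const double s = qp_step(g, Gbo[k], Dbo[k], lr, mu);
      bo[k] += s; Dbo[k] = s; Gbo[k] = g;
    }
  }
}
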