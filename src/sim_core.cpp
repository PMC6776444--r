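// Time-stepping core for the coupled attractor stack.
//
// The recurrent and coupling sums are linear convolutions with compactly
// supported radial kernels, evaluated by zero-padded FFTs (FFTW, with plans
// cached for the whole run). The subpopulation output shift xi and the
// per-neuron coupling-output jitter act on the *source* field, so each
// network needs only two real transforms per step: one of the
// shift-accumulated field (recurrent input) and one of the plain/scattered
// field (as a coupling source). Both are packed into a single complex FFT
// and unpacked on the fly while applying the kernel spectra. Kernel spectra
// arrive pre-scaled by 1/P^2 so the inverse transform needs no
// normalization. Rectified Euler updates then run per element.
#include <RcppArmadillo.h>
#include <fftw3.h>
using namespace Rcpp;

typedef std::complex<double> cxd;

struct FFT2 {
  int P;
  arma::cx_mat fin, fout, bin, bout;
  fftw_plan pf, pb;
  explicit FFT2(int P_)
      : P(P_), fin(P_, P_, arma::fill::zeros), fout(P_, P_),
        bin(P_, P_), bout(P_, P_) {
    pf = fftw_plan_dft_2d(P, P,
                          reinterpret_cast<fftw_complex*>(fin.memptr()),
                          reinterpret_cast<fftw_complex*>(fout.memptr()),
                          FFTW_FORWARD, FFTW_ESTIMATE);
    pb = fftw_plan_dft_2d(P, P,
                          reinterpret_cast<fftw_complex*>(bin.memptr()),
                          reinterpret_cast<fftw_complex*>(bout.memptr()),
                          FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FFT2() { fftw_destroy_plan(pf); fftw_destroy_plan(pb); }
};

// [[Rcpp::export]]
List sim_core_cpp(List rates0, List wfft_r, List ufft_r,
                  IntegerVector src_a, IntegerVector src_b,
                  const arma::mat& drive, const arma::mat& dvx,
                  const arma::mat& dvy, const arma::mat& vel,
                  double dt_over_tau, int P, int m0, int xi,
                  const arma::imat& subpop,
                  double noise_sd, bool spiking, double spike_fac,
                  List lesion_r, List cshift_r,
                  const arma::imat& rec_idx, int rec_every) {
  const int h = rates0.size();
  std::vector<arma::mat> S(h);
  for (int z = 0; z < h; ++z) S[z] = as<arma::mat>(rates0[z]);
  const int n = S[0].n_rows;
  const int nsteps = vel.n_rows;

  std::vector<arma::cx_mat> W(h), U(h);
  for (int z = 0; z < h; ++z) {
    W[z] = as<arma::cx_mat>(wfft_r[z]);
    if (!Rf_isNull(ufft_r[z])) U[z] = as<arma::cx_mat>(ufft_r[z]);
  }

  const bool lesioned = lesion_r.size() > 0;
  std::vector<arma::mat> M(h);
  if (lesioned) for (int z = 0; z < h; ++z) M[z] = as<arma::mat>(lesion_r[z]);

  const bool cshift = cshift_r.size() > 0;
  std::vector<arma::imat> CS(h);
  if (cshift) for (int z = 0; z < h; ++z) CS[z] = as<arma::imat>(cshift_r[z]);

  std::vector<bool> is_src(h, false);
  for (int z = 0; z < h; ++z) {
    if (src_a[z] > 0) is_src[src_a[z] - 1] = true;
    if (src_b[z] > 0) is_src[src_b[z] - 1] = true;
  }

  const int exk[4] = {1, -1, 0, 0}, eyk[4] = {0, 0, 1, -1};
  const int csx[4] = {1, 1, -1, -1}, csy[4] = {1, -1, 1, -1};
  std::vector<int> rev(P);
  rev[0] = 0;
  for (int i = 1; i < P; ++i) rev[i] = P - i;

  const int nrec = rec_idx.n_rows;
  const int nrecsteps = (rec_every > 0) ? nsteps / rec_every : 0;
  arma::mat rec(nrecsteps, nrec > 0 ? nrec : 1, arma::fill::zeros);
  int irec = 0;
  // in spiking mode, recorded neurons report their Poisson spike counts
  std::vector<double> rec_buf(nrec > 0 ? nrec : 1, 0.0);

  FFT2 fft(P);
  const int wlo = m0 - xi - 1 < 0 ? 0 : m0 - xi - 1;
  const int whi = m0 + n + xi;  // inclusive upper bound of the used window
  std::vector<arma::cx_mat> Gh(h), Th(h);
  for (int z = 0; z < h; ++z) {
    Th[z].set_size(P, P);
    if (is_src[z]) Gh[z].set_size(P, P);
  }
  arma::mat p(n, n);

  for (int t = 0; t < nsteps; ++t) {
    const double Vx = vel(t, 0), Vy = vel(t, 1);

    for (int z = 0; z < h; ++z) {
      const bool needG = is_src[z];
      const arma::mat* ps;
      if (spiking) {
        for (int j = 0; j < n; ++j)
          for (int i = 0; i < n; ++i)
            p(i, j) = R::rpois(S[z](i, j) * spike_fac) / spike_fac;
        ps = &p;
      } else {
        ps = &S[z];
      }
      const arma::mat& sf = *ps;
      if (spiking && rec_every > 0 && ((t + 1) % rec_every == 0)) {
        for (int q = 0; q < nrec; ++q)
          if (rec_idx(q, 0) - 1 == z)
            rec_buf[q] = sf(rec_idx(q, 1) - 1, rec_idx(q, 2) - 1) * spike_fac;
      }
      // only the window touched by the field (plus shift margins) is ever
      // nonzero; zero and refill just that block
      fft.fin.submat(wlo, wlo, whi, whi).zeros();
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) {
          const double v = sf(i, j);
          if (v == 0.0) continue;
          const int k = subpop(i, j) - 1;
          fft.fin(m0 + i - xi * exk[k], m0 + j - xi * eyk[k]) += v;
        }
      }
      if (needG) {
        if (cshift) {
          for (int j = 0; j < n; ++j)
            for (int i = 0; i < n; ++i) {
              const int k = CS[z](i, j) - 1;
              fft.fin(m0 + i + csx[k], m0 + j + csy[k]) += cxd(0.0, sf(i, j));
            }
        } else {
          for (int j = 0; j < n; ++j)
            for (int i = 0; i < n; ++i)
              fft.fin(m0 + i, m0 + j) += cxd(0.0, sf(i, j));
        }
      }
      fftw_execute(fft.pf);
      // fused: unpack the packed spectra and apply the recurrent kernel
      const cxd* Ch = fft.fout.memptr();
      const cxd* Wz = W[z].memptr();
      cxd* Tz = Th[z].memptr();
      cxd* Gz = needG ? Gh[z].memptr() : nullptr;
      for (int j = 0; j < P; ++j) {
        const int jr = rev[j];
        const cxd* colf = Ch + (size_t)j * P;
        const cxd* colr = Ch + (size_t)jr * P;
        cxd* tcol = Tz + (size_t)j * P;
        const cxd* wcol = Wz + (size_t)j * P;
        if (needG) {
          cxd* gcol = Gz + (size_t)j * P;
          for (int i = 0; i < P; ++i) {
            const cxd a = colf[i], b = std::conj(colr[rev[i]]);
            tcol[i] = wcol[i] * (0.5 * (a + b));
            gcol[i] = cxd(0.0, -0.5) * (a - b);
          }
        } else {
          for (int i = 0; i < P; ++i) {
            const cxd a = colf[i], b = std::conj(colr[rev[i]]);
            tcol[i] = wcol[i] * (0.5 * (a + b));
          }
        }
      }
    }

    for (int z = 0; z < h; ++z) {
      if (src_a[z] > 0) Th[z] += U[src_a[z] - 1] % Gh[src_a[z] - 1];
      if (src_b[z] > 0) Th[z] += U[src_b[z] - 1] % Gh[src_b[z] - 1];
    }

    for (int z = 0; z < h; z += 2) {
      const bool pair = (z + 1 < h);
      if (pair) {
        fft.bin = Th[z] + cxd(0.0, 1.0) * Th[z + 1];
      } else {
        fft.bin = Th[z];
      }
      fftw_execute(fft.pb);
      for (int which = 0; which <= (pair ? 1 : 0); ++which) {
        const int zz = z + which;
        arma::mat& Sz = S[zz];
        for (int j = 0; j < n; ++j) {
          for (int i = 0; i < n; ++i) {
            const cxd c = fft.bout(m0 + i, m0 + j);
            double tot = (which == 0 ? c.real() : c.imag());
            tot += drive(i, j) + dvx(i, j) * Vx + dvy(i, j) * Vy;
            if (tot < 0.0) tot = 0.0;
            Sz(i, j) += dt_over_tau * (tot - Sz(i, j));
          }
        }
        if (noise_sd > 0.0) {
          NumericVector eta = rnorm(n * n, 0.0, noise_sd);
          double* sp = Sz.memptr();
          for (int q = 0; q < n * n; ++q) {
            sp[q] += eta[q];
            if (sp[q] < 0.0) sp[q] = 0.0;
          }
        }
        if (lesioned) Sz %= M[zz];
      }
    }

    if (rec_every > 0 && ((t + 1) % rec_every == 0)) {
      for (int q = 0; q < nrec; ++q)
        rec(irec, q) = spiking ? rec_buf[q]
          : S[rec_idx(q, 0) - 1](rec_idx(q, 1) - 1, rec_idx(q, 2) - 1);
      ++irec;
    }
    if (t % 500 == 0) Rcpp::checkUserInterrupt();
  }

  List out_rates(h);
  for (int z = 0; z < h; ++z) out_rates[z] = S[z];
  return List::create(_["rates"] = out_rates, _["rec"] = rec);
}
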