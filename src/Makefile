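# Custom makefile: the conda-forge cross toolchain configured in this R
# build targets glibc 2.38 while the host runtime is glibc 2.35, so objects
# it produces cannot be dyn.load()ed.  Build with the system compiler
# instead (plain C++17 + Rcpp headers; no further dependencies).
RCPP_INC = $(shell "$(R_HOME)/bin/Rscript" --vanilla -e 'cat(system.file("include", package = "Rcpp"))')
LOCAL_CXX = g++ -std=gnu++17
LOCAL_FLAGS = -I"$(R_INCLUDE_DIR)" -I"$(RCPP_INC)" -O2 -fPIC

all: cardiosim.so

cardiosim.so: core.o RcppExports.o
	$(LOCAL_CXX) -shared -o $@ core.o RcppExports.o -L"$(R_HOME)/lib" -lR

core.o: core.cpp
	$(LOCAL_CXX) $(LOCAL_FLAGS) -c core.cpp -o core.o

RcppExports.o: RcppExports.cpp
	$(LOCAL_CXX) $(LOCAL_FLAGS) -c RcppExports.cpp -o RcppExports.o

clean:
	rm -f *.o cardiosim.so
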